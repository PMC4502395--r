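makeRpkmSE <- function(mat, conditions) {
  SummarizedExperiment::SummarizedExperiment(
    assays = list(rpkm = mat),
    colData = S4Vectors::DataFrame(condition = conditions,
                                   row.names = colnames(mat)))
}

makeCountsSE <- function(mat, totals,
                         conditions = rep("root", ncol(mat))) {
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = mat),
    colData = S4Vectors::DataFrame(
      library_id = colnames(mat), condition = conditions,
      replicate = seq_len(ncol(mat)), total_mapped = totals,
      row.names = colnames(mat)))
}

test_that("RPKM formula, zero mapping and scaling law", {
  m <- matrix(c(10L, 0L), 2, 1, dimnames = list(c("g1", "g2"), "L1"))
  se <- makeCountsSE(m, totals = 1e6)
  r <- SummarizedExperiment::assay(
    computeRpkm(se, c(g1 = 1000, g2 = 500)), "rpkm")
  expect_equal(r["g1", "L1"], 10)
  expect_equal(r["g2", "L1"], 0)
  # doubling the library total halves every RPKM
  se2 <- makeCountsSE(m, totals = 2e6)
  r2 <- SummarizedExperiment::assay(
    computeRpkm(se2, c(g1 = 1000, g2 = 500)), "rpkm")
  expect_equal(r2["g1", "L1"], 5)
  expect_error(computeRpkm(se, c(g1 = 1000)), "no cDNA length")
})

test_that("RPKM conserves counts: sum(RPKM x L) x N / 1e9 = sum counts", {
  cfg <- simulationConfig(seed = 19, nGenes = 30L)
  sim <- simulateGenome(cfg)
  counts <- simulateCounts(sim$truth, sim$models, cfg)
  L <- cdsLengths(sim$models)
  rpkm <- computeRpkm(counts, L)
  m <- SummarizedExperiment::assay(counts)
  r <- SummarizedExperiment::assay(rpkm)
  N <- SummarizedExperiment::colData(counts)$total_mapped
  for (j in seq_len(ncol(m))) {
    recovered <- sum(r[, j] * L[rownames(r)]) * N[j] / 1e9
    expect_equal(recovered, sum(m[, j]), tolerance = 1e-6)
  }
})

test_that("replicate aggregation is the arithmetic mean, order-invariant", {
  m <- matrix(c(2, 4, 7), 1, 3,
              dimnames = list("g", c("a1", "a2", "b1")))
  se <- makeRpkmSE(m, c("root", "root", "leaf"))
  agg <- SummarizedExperiment::assay(aggregateReplicates(se))
  expect_equal(agg["g", "root"], 3)
  expect_equal(agg["g", "leaf"], 7)
  sePerm <- makeRpkmSE(m[, c(3, 1, 2), drop = FALSE],
                       c("leaf", "root", "root"))
  aggPerm <- SummarizedExperiment::assay(aggregateReplicates(sePerm))
  expect_equal(aggPerm[, colnames(agg)], agg[1, ])
})

test_that("specificity requires exact zeros elsewhere, with no minimum", {
  m <- matrix(c(0, 0, 0.075, 0,
                0, 0, 0, 0,
                1, 1, 1, 1), 3, 4, byrow = TRUE,
              dimnames = list(c("gLow", "gOff", "gFlat"),
                              c("flower", "leaf", "root", "stem")))
  se <- makeRpkmSE(m, colnames(m))
  flags <- detectionAndSpecificity(se)
  expect_equal(flags$specific_to[flags$gene_id == "gLow"], "root")
  expect_equal(flags$n_detected[flags$gene_id == "gOff"], 0)
  expect_true(is.na(flags$specific_to[flags$gene_id == "gOff"]))
  expect_equal(flags$detected_in[flags$gene_id == "gFlat"],
               "flower,leaf,root,stem")
  expect_true(is.na(flags$specific_to[flags$gene_id == "gFlat"]))
})

test_that("enrichment filter boundary uses >= fold and > minRpkm", {
  m <- matrix(c(4, 2, 1, 0,
                4, 2.1, 1, 0,
                1, 0.4, 0, 0,
                8, 0, 0, 0), 4, 4, byrow = TRUE,
              dimnames = list(c("pass", "boundary", "low", "zeroOthers"),
                              c("root", "flower", "leaf", "stem")))
  se <- makeRpkmSE(m, colnames(m))
  got <- enrichmentFilter(se, "root", c("flower", "leaf", "stem"))
  expect_true("pass" %in% got)          # 4 >= 2 x 2
  expect_false("boundary" %in% got)     # 4 < 2 x 2.1
  expect_false("low" %in% got)          # target not > 1
  expect_true("zeroOthers" %in% got)
  # monotone in fold: larger fold gives a subset
  got4 <- enrichmentFilter(se, "root", c("flower", "leaf", "stem"), fold = 4)
  expect_true(all(got4 %in% got))
})

test_that("MeJA response handles zero baselines via the pseudocount", {
  m <- matrix(c(1, 4,
                0, 3,
                3, 3,
                0, 0.5), 4, 2, byrow = TRUE,
              dimnames = list(c("up", "fromZero", "flat", "weak"),
                              c("T0", "T12")))
  se <- makeRpkmSE(m, colnames(m))
  got <- mejaResponse(se)
  expect_setequal(got, c("up", "fromZero"))
  # (4 + .1)/(1 + .1) = 3.7 >= 2; (3+.1)/(0+.1) = 31; flat ratio 1;
  # weak fails the min-RPKM gate
})

test_that("hierarchical clustering merges identical profiles first and
           matches a naive average-linkage oracle", {
  m <- matrix(c(1, 2, 3, 4,
                1, 2, 3, 4,
                4, 3, 2, 1), 3, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"),
                              c("flower", "leaf", "root", "stem")))
  se <- makeRpkmSE(m, colnames(m))
  cl <- hierarchicalCluster(se)
  expect_equal(cl$height[1], 0, tolerance = 1e-12)
  expect_equal(sort(cl$hclust$merge[1, ]), c(-2, -1))

  set.seed(61)
  mm <- matrix(stats::rlnorm(6 * 4), 6, 4,
               dimnames = list(paste0("g", 1:6),
                               c("flower", "leaf", "root", "stem")))
  se2 <- makeRpkmSE(mm, colnames(mm))
  cl2 <- hierarchicalCluster(se2, distance = "correlation",
                             linkage = "average")
  lm <- log2(mm + 1)
  d <- 1 - stats::cor(t(lm))
  expect_equal(sort(cl2$height), naiveAverageLinkHeights(d),
               tolerance = 1e-9)

  # zero-variance genes get distance 1 and are reported
  mz <- rbind(mm, gz = rep(2, 4))
  clz <- hierarchicalCluster(makeRpkmSE(mz, colnames(mz)))
  expect_equal(clz$zero_variance, "gz")
})

test_that("near-zero dispersion recovers the planted filter truth exactly", {
  cfg <- simulationConfig(seed = 29, nGenes = 40L, dispersion = 0)
  sim <- simulateGenome(cfg)
  counts <- simulateCounts(sim$truth, sim$models, cfg)
  cond <- aggregateReplicates(computeRpkm(counts, cdsLengths(sim$models)))
  exp_ <- truthExpectedFlags(sim$truth)

  spec <- detectionAndSpecificity(cond)
  expect_setequal(spec$gene_id[!is.na(spec$specific_to) &
                                 spec$specific_to == "root"],
                  exp_$root_specific)
  expect_setequal(spec$gene_id[!is.na(spec$specific_to) &
                                 spec$specific_to == "flower"],
                  exp_$flower_specific)
  expect_setequal(enrichmentFilter(cond, "root",
                                   c("flower", "leaf", "stem")),
                  exp_$root_enriched)
  expect_setequal(enrichmentFilter(cond, "periderm", c("phloem", "xylem")),
                  exp_$periderm_enriched)
  expect_setequal(mejaResponse(cond), exp_$meja_up)
})
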