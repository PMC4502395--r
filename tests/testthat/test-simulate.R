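cfgSmall <- simulationConfig(seed = 7, nGenes = 20L, nContigs = 2L)

test_that("identical config and seed give byte-identical outputs", {
  s1 <- simulateGenome(cfgSmall)
  s2 <- simulateGenome(cfgSmall)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$truth, s2$truth)
  c1 <- simulateCounts(s1$truth, s1$models, cfgSmall)
  c2 <- simulateCounts(s2$truth, s2$models, cfgSmall)
  expect_identical(SummarizedExperiment::assay(c1),
                   SummarizedExperiment::assay(c2))
})

test_that("emitted CDS are valid ORFs consistent with the truth table", {
  sim <- simulateGenome(cfgSmall)
  cdna <- spliceCds(sim$genome, sim$models)
  for (g in names(cdna)) expect_true(validateOrf(cdna[[g]])$ok)
  # translation matches the emitted proteome
  prot <- Biostrings::translate(Biostrings::subseq(
    cdna, 1, Biostrings::width(cdna) - 3L))
  expect_identical(as.character(prot),
                   as.character(sim$proteome)[names(cdna)])
  # truth exon counts equal GFF segment counts; cDNA lengths agree
  expect_equal(unname(exonCounts(sim$models)[sim$truth$gene_id]),
               sim$truth$n_exons)
  expect_equal(unname(cdsLengths(sim$models)[sim$truth$gene_id]),
               sim$truth$cdna_length)
  expect_true(all(sim$truth$n_exons >= 1 & sim$truth$n_exons <= 12))
})

test_that("organ-specific classes are hard zero outside their organ", {
  cfg <- simulationConfig(seed = 21, nGenes = 30L)
  sim <- simulateGenome(cfg)
  counts <- simulateCounts(sim$truth, sim$models, cfg)
  m <- SummarizedExperiment::assay(counts)
  cond <- SummarizedExperiment::colData(counts)$condition
  rootSpec <- sim$truth$gene_id[sim$truth$class == "root_specific"]
  expect_gt(length(rootSpec), 0)
  away <- cond %in% c("flower", "leaf", "stem", "T0", "T12")
  expect_true(all(m[rootSpec, away] == 0))
  flowerSpec <- sim$truth$gene_id[sim$truth$class == "flower_specific"]
  expect_true(all(m[flowerSpec, cond != "flower"] == 0))
})

test_that("boosted library means track the configured fold", {
  # Monte-Carlo over many genes: mean count in the boosted condition over
  # the matched baseline condition approximates the planted fold
  cfg <- simulationConfig(seed = 5, nGenes = 250L, nContigs = 4L,
                          classCounts = c(meja_up = 120L))
  sim <- simulateGenome(cfg)
  counts <- simulateCounts(sim$truth, sim$models, cfg)
  m <- SummarizedExperiment::assay(counts)
  up <- sim$truth$gene_id[sim$truth$class == "meja_up"]
  ratio <- sum(m[up, "T12_1"]) / sum(m[up, "T0_1"])
  # depths differ between the two libraries; normalise them out
  depths <- SummarizedExperiment::colData(counts)$total_mapped
  names(depths) <- colnames(m)
  ratio <- ratio * depths[["T0_1"]] / depths[["T12_1"]]
  expect_equal(unname(ratio), cfg@mejaFold, tolerance = 0.05)
})

test_that("dispersion -> 0 gives Poisson-like counts (variance ~ mean)", {
  cfg <- simulationConfig(seed = 9, nGenes = 200L, dispersion = 0,
                          classCounts = c(meja_up = 0L))
  sim <- simulateGenome(cfg)
  counts <- simulateCounts(sim$truth, sim$models, cfg)
  m <- SummarizedExperiment::assay(counts)
  cd <- SummarizedExperiment::colData(counts)
  cond <- cd$condition
  # replicate libraries differ in depth; rescale to a common depth before
  # pooling the Fano factor across genes within one condition
  depthScaled <- function(mat, cdat) {
    sub <- mat[, cdat$condition == "periderm"]
    N <- cdat$total_mapped[cdat$condition == "periderm"]
    sweep(sub, 2, mean(N) / N, `*`)
  }
  sub <- depthScaled(m, cd)
  mu <- rowMeans(sub)
  v <- apply(sub, 1, var)
  keep <- mu > 10
  fano <- mean(v[keep] / mu[keep])
  expect_equal(fano, 1, tolerance = 0.25)
  # and the default dispersion is clearly super-Poissonian at these depths
  cfg2 <- simulationConfig(seed = 9, nGenes = 200L,
                           classCounts = c(meja_up = 0L))
  sim2 <- simulateGenome(cfg2)
  cnt2 <- simulateCounts(sim2$truth, sim2$models, cfg2)
  sub2 <- depthScaled(SummarizedExperiment::assay(cnt2),
                      SummarizedExperiment::colData(cnt2))
  mu2 <- rowMeans(sub2); v2 <- apply(sub2, 1, var)
  expect_gt(mean(v2[mu2 > 10] / mu2[mu2 > 10]), 5)
})

test_that("planted promoter E-boxes are exactly recoverable", {
  cfg <- simulationConfig(seed = 13, nGenes = 50L,
                          promoterEboxFraction = 0.6)
  sim <- simulateGenome(cfg)
  expect_equal(sum(sim$truth$ebox_planted > 0), 30)
  prom <- extractPromoters(sim$genome, sim$models, length = 500L)
  ebox <- data.frame(name = "E-box", pattern = "CANNTG", description = "")
  hits <- scanElements(prom, ebox)
  tallied <- summarizeElements(hits, sim$truth$gene_id)
  got <- rowSums(tallied$per_gene)[sim$truth$gene_id]
  expect_equal(unname(got), sim$truth$ebox_planted)
  expect_equal(tallied$n_with_hit, sum(sim$truth$ebox_planted > 0))
})
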