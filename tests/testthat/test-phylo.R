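test_that("p-distance counts mismatches over comparable sites", {
  expect_equal(pDistance(c(a = "AAAA", b = "AAAT"))["a", "b"], 0.25)
  expect_equal(pDistance(c(a = "A-AA", b = "ATAA"))["a", "b"], 0)  # 3 sites
  d <- pDistance(c(a = "AAAA", b = "AATT", c = "TTTT"))
  expect_equal(unname(diag(d)), c(0, 0, 0))
  expect_equal(d, t(d))
  expect_error(pDistance(c(a = "--AA", b = "TT--")), "zero comparable")
  # complete deletion drops columns gapped anywhere
  dc <- pDistance(c(a = "A-AT", b = "ATAT", c = "ATAA"),
                  deletion = "complete")
  expect_equal(dc["a", "b"], 0)      # columns 1,3,4 kept; col2 dropped
})

test_that("three-taxon NJ uses the closed-form branch lengths", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(d)
  got <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                         tr$tip.label)
  expect_equal(got[["A"]], (3 + 4 - 5) / 2)
  expect_equal(got[["B"]], (3 + 5 - 4) / 2)
  expect_equal(got[["C"]], (4 + 5 - 3) / 2)
})

test_that("NJ exactly recovers additive trees (topology and lengths)", {
  set.seed(41)
  for (i in 1:60) {
    n <- sample(4:8, 1)
    ref <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 2))
    d <- ape::cophenetic.phylo(ref)
    d <- d[sort(rownames(d)), sort(colnames(d))]
    tr <- njTree(d)
    expect_setequal(bipartitions(tr), bipartitions(ape::unroot(ref)))
    # recovered patristic distances reproduce the input exactly
    dd <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
    expect_equal(dd, d, tolerance = 1e-6)
  }
})

test_that("NJ matches the reference implementation on noisy matrices", {
  set.seed(42)
  for (i in 1:10) {
    n <- 7
    base <- ape::cophenetic.phylo(ape::rtree(n))
    noise <- matrix(stats::runif(n * n, 0, 0.05), n)
    noise <- noise + t(noise); diag(noise) <- 0
    d <- base + noise
    mine <- njTree(d)
    ref <- ape::nj(stats::as.dist(d))
    expect_setequal(bipartitions(mine), bipartitions(ape::unroot(ref)))
  }
})

test_that("NJ rejects asymmetric input and clamps negative branches", {
  d <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(njTree(d), "symmetric")
  # a strongly non-additive matrix can induce negative estimates; the
  # output must still be non-negative everywhere
  set.seed(43)
  n <- 6
  m <- matrix(stats::runif(n * n, 0.01, 1), n)
  m <- (m + t(m)) / 2; diag(m) <- 0
  rownames(m) <- colnames(m) <- letters[1:n]
  tr <- njTree(m)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports are deterministic, order-invariant and sane", {
  cfg <- simulationConfig(seed = 3, nGenes = 16L, nContigs = 2L)
  sim <- simulateGenome(cfg)
  fam <- identifyFamily(sim$proteome, sim$models, sim$pssm,
                        genome = sim$genome)
  doms <- substr(as.character(sim$proteome[fam$gene_id]),
                 fam$domain_start, fam$domain_end)
  names(doms) <- fam$name
  aln <- progressiveAlign(doms)

  t1 <- bootstrapSupports(aln, replicates = 60, seed = 9)
  t2 <- bootstrapSupports(aln, replicates = 60, seed = 9)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))

  perm <- sample(length(aln))
  t3 <- bootstrapSupports(aln[perm], replicates = 60, seed = 9)
  expect_identical(ape::write.tree(t1), ape::write.tree(t3))

  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))

  t0 <- bootstrapSupports(aln, replicates = 0)
  expect_null(t0$node.label)
})

test_that("a clean two-clade alignment gets full support", {
  aln <- c(a = "AAAAAAAAAACCCCCCCCCC", b = "AAAAAAAAAACCCCCCCCCC",
           c = "TTTTTTTTTTGGGGGGGGGG", d = "TTTTTTTTTTGGGGGGGGGG",
           e = "TTTTTTTTTTGGGGGGGGGA")
  tr <- bootstrapSupports(aln, replicates = 100, seed = 2)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(100 %in% sup)   # the ab | cde split is in every replicate
})

test_that("subfamily assignment: anchors expand to supported clades, the
           depth cut partitions the rest into clades", {
  # hand-built rooted tree with supports
  txt <- "((A:0.1,B:0.1)95:0.9,((C:0.1,D:0.1)99:0.4,E:0.5)90:0.5);"
  tr <- ape::read.tree(text = txt)
  lab <- assignSubfamilies(tr, anchors = c(C = "R"), minSupport = 50)
  expect_equal(unname(lab[c("C", "D", "E")]), rep("R", 3))
  expect_equal(length(unique(lab[c("A", "B")])), 1L)
  expect_false("R" %in% lab[c("A", "B")])

  # conflicting anchors inside one supported clade
  expect_error(assignSubfamilies(tr, anchors = c(C = "R", D = "O"),
                                 minSupport = 50),
               "conflict")

  # no anchors, star tree: every leaf its own subfamily
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  labStar <- assignSubfamilies(star)
  expect_equal(length(unique(labStar)), 4L)

  # partitions are clades: each label's leaf set appears as a bipartition
  # side or a trivial group
  cfg <- simulationConfig(seed = 3, nGenes = 16L, nContigs = 2L)
  sim <- simulateGenome(cfg)
  fam <- identifyFamily(sim$proteome, sim$models, sim$pssm,
                        genome = sim$genome)
  doms <- substr(as.character(sim$proteome[fam$gene_id]),
                 fam$domain_start, fam$domain_end)
  names(doms) <- fam$name
  tr2 <- bootstrapSupports(progressiveAlign(doms), replicates = 30, seed = 1)
  lab2 <- assignSubfamilies(tr2)
  rooted <- phangorn::midpoint(tr2)
  ntip <- length(rooted$tip.label)
  allNodes <- seq_len(ntip + rooted$Nnode)
  clades <- vapply(phangorn::Descendants(rooted, allNodes, "tips"),
                   function(tp) paste(sort(rooted$tip.label[tp]),
                                      collapse = ","), character(1))
  for (l in unique(lab2)) {
    grp <- paste(sort(names(lab2)[lab2 == l]), collapse = ",")
    expect_true(grp %in% clades, info = l)
  }
})

test_that("subfamily partition refines the planted domain variants", {
  cfg <- simulationConfig(seed = 3, nGenes = 40L)
  sim <- simulateGenome(cfg)
  fam <- identifyFamily(sim$proteome, sim$models, sim$pssm,
                        genome = sim$genome)
  doms <- substr(as.character(sim$proteome[fam$gene_id]),
                 fam$domain_start, fam$domain_end)
  names(doms) <- fam$name
  tr <- bootstrapSupports(progressiveAlign(doms), replicates = 40, seed = 1)
  lab <- assignSubfamilies(tr)
  variant <- stats::setNames(
    sim$truth$variant[match(fam$gene_id, sim$truth$gene_id)], fam$name)
  # every subfamily is pure with respect to the planted variant
  for (l in unique(lab)) {
    expect_equal(length(unique(variant[names(lab)[lab == l]])), 1L,
                 info = l)
  }
  expect_gte(length(unique(lab)), cfg@nVariants)
})
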