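test_that("PSSM construction matches hand arithmetic and drops gap columns", {
  aln <- Biostrings::AAStringSet(c(s1 = "AC", s2 = "AC"))
  p <- buildPssm(aln, pseudocount = 1)
  # count 2 of A among 2 rows, pseudocount 1, uniform background 1/20
  expect_equal(p@scores[1, "A"], log2((2 + 1) / (2 + 20) / 0.05))
  expect_equal(p@scores[2, "C"], log2((2 + 1) / (2 + 20) / 0.05))
  expect_equal(p@scores[1, "W"], log2((0 + 1) / (2 + 20) / 0.05))

  gappy <- Biostrings::AAStringSet(c(s1 = "A-C", s2 = "A-C", s3 = "A-C"))
  expect_equal(nrow(buildPssm(gappy)@scores), 2L)

  # pseudocount -> infinity flattens all scores to 0 bits
  flat <- buildPssm(aln, pseudocount = 1e9)
  expect_equal(max(abs(flat@scores)), 0, tolerance = 1e-6)

  expect_error(buildPssm(Biostrings::AAStringSet(c(s1 = "AC"))), "at least 2")
})

test_that("scanProtein finds planted consensus and equals brute-force max", {
  aln <- readFasta(bhlhSeedAlignmentPath(), "AA")
  pssm <- buildPssm(aln)
  cons <- pssmConsensus(pssm)
  prot <- paste0(strrep("A", 17), cons, strrep("A", 25))
  hit <- scanProtein(pssm, prot)
  expect_equal(hit$start, 18L)
  expect_equal(hit$end, 17L + nchar(cons))

  expect_null(scanProtein(pssm, "MKLV"))  # shorter than the PSSM

  # brute-force window oracle on random proteins and a short PSSM
  set.seed(31)
  small <- buildPssm(Biostrings::AAStringSet(c(
    a = "MKRLVDEAYQSNWTG", b = "MKRIVDEAYQSNWSG", c = "MKRLVEEAYRSNWTG")))
  for (i in 1:20) {
    prot <- paste(sample(colnames(small@scores), 60, replace = TRUE),
                  collapse = "")
    got <- scanProtein(small, prot)
    chars <- strsplit(prot, "")[[1]]
    L <- nrow(small@scores)
    naive <- vapply(seq_len(60 - L + 1), function(s)
      sum(small@scores[cbind(seq_len(L),
                             match(chars[s:(s + L - 1)],
                                   colnames(small@scores)))]),
      numeric(1))
    expect_equal(got$score, max(naive))
    # smallest start among (numerically) tied maxima
    expect_equal(got$start, min(which(naive >= max(naive) - 1e-9)))
  }
})

test_that("ORF validation follows the codon rules", {
  expect_true(validateOrf("ATGGCCTAA")$ok)
  expect_false(validateOrf("ATGTAATAA")$ok)   # internal stop
  expect_match(validateOrf("ATGTAATAA")$reason, "internal stop")
  expect_false(validateOrf("ATGGCCTA")$ok)    # length
  expect_false(validateOrf("TTGGCCTAA")$ok)   # start
  expect_false(validateOrf("ATGGCCAAA")$ok)   # no stop
  expect_match(validateOrf("ATGGNCTAA")$reason, "ambiguous")
})

test_that("family identification recovers planted genes, is threshold-monotone
           and names deterministically by coordinate", {
  cfg <- simulationConfig(seed = 7, nGenes = 20L, nContigs = 2L)
  sim <- simulateGenome(cfg)
  fam <- identifyFamily(sim$proteome, sim$models, sim$pssm,
                        genome = sim$genome)
  planted <- sim$truth$gene_id[sim$truth$is_bhlh]
  expect_setequal(fam$gene_id, planted)

  # raising the threshold never adds members
  thr <- S4Vectors::metadata(fam)$threshold_bits
  for (extra in c(5, 20, 60)) {
    famUp <- identifyFamily(sim$proteome, sim$models, sim$pssm,
                            genome = sim$genome, thresholdBits = thr + extra)
    expect_true(all(famUp$gene_id %in% fam$gene_id))
  }
  famInf <- identifyFamily(sim$proteome, sim$models, sim$pssm,
                           genome = sim$genome, thresholdBits = Inf)
  expect_equal(nrow(famInf), 0L)

  # naming is independent of proteome input order
  shuffled <- sim$proteome[sample(length(sim$proteome))]
  fam2 <- identifyFamily(shuffled, sim$models, sim$pssm,
                         genome = sim$genome, thresholdBits = thr)
  expect_identical(as.data.frame(fam), as.data.frame(fam2))
  # and ordinals follow (contig, start)
  contigs <- geneContig(sim$models)[fam$gene_id]
  starts <- vapply(cdsBy(sim$models)[fam$gene_id],
                   function(gr) min(GenomicRanges::start(gr)), integer(1))
  expect_false(is.unsorted(order(contigs, starts)))

  # proteins without a gene model are excluded with a warning
  orphan <- c(sim$proteome,
              Biostrings::AAStringSet(c(orphanP = "MKKLLE")))
  expect_warning(identifyFamily(orphan, sim$models, sim$pssm,
                                thresholdBits = thr),
                 "without a gene model")
})
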