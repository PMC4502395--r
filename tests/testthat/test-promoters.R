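test_that("promoter extraction anchors at the translation start", {
  genome <- Biostrings::DNAStringSet(c(c1 = paste(
    rep(c("A", "C", "G", "T"), length.out = 300), collapse = "")))
  gm <- toyModels(list(
    gPlus = list(contig = "c1", strand = "+", starts = 101, ends = 160),
    gEdge = list(contig = "c1", strand = "+", starts = 1, ends = 90)))
  prom <- extractPromoters(genome, gm, length = 50L)
  p <- prom[prom$gene_id == "gPlus", ]
  expect_equal(p$sequence,
               as.character(Biostrings::subseq(genome[["c1"]], 51, 100)))
  expect_false(p$truncated)
  e <- prom[prom$gene_id == "gEdge", ]
  expect_equal(e$sequence, "")
  expect_true(e$truncated)
})

test_that("minus-strand promoters are the reverse complement of the
           downstream flank", {
  contig <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(c1 = contig))
  gm <- toyModels(list(
    gMinus = list(contig = "c1", strand = "-", starts = 5, ends = 16)))
  prom <- extractPromoters(genome, gm, length = 10L)
  expected <- as.character(Biostrings::reverseComplement(
    Biostrings::subseq(genome[["c1"]], 17, 26)))
  expect_equal(prom$sequence, expected)
  expect_equal(prom$length, 10L)
})

test_that("element scanning matches examples and de-duplicates palindromes", {
  prom <- data.frame(gene_id = "g", sequence = "TTCAGGTGTT")
  ebox <- data.frame(name = "E-box", pattern = "CANNTG")
  hits <- scanElements(prom, ebox)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$position, 3L)
  expect_equal(hits$match, "CAGGTG")

  pal <- scanElements(data.frame(gene_id = "g", sequence = "CACGTG"), ebox)
  expect_equal(nrow(pal), 1L)        # palindrome reported once
  expect_equal(pal$strand, "+")

  expect_error(scanElements(prom, data.frame(name = "bad", pattern = "CAX")),
               "IUPAC")
})

test_that("palindromic patterns give identical hits on either strand
           setting; every reported substring re-matches its pattern", {
  set.seed(83)
  ebox <- data.frame(name = "E-box", pattern = "CANNTG")
  for (i in 1:20) {
    prom <- data.frame(gene_id = "g", sequence = paste(
      sample(c("A", "C", "G", "T"), 200, TRUE), collapse = ""))
    both <- scanElements(prom, ebox, bothStrands = TRUE)
    fwd <- scanElements(prom, ebox, bothStrands = FALSE)
    expect_identical(both, fwd)
    for (k in seq_len(nrow(both)))
      expect_equal(length(naiveIupacHits(both$match[k], "CANNTG")), 1L)
  }
})

test_that("hit positions equal a naive position-by-position matcher", {
  set.seed(84)
  patterns <- c("CANNTG", "TATAWAW", "CNGTTR")
  for (i in 1:30) {
    seq <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    prom <- data.frame(gene_id = "g", sequence = seq)
    for (p in patterns) {
      got <- scanElements(prom, data.frame(name = p, pattern = p),
                          bothStrands = FALSE)
      expect_equal(got$position, naiveIupacHits(seq, p), info = p)
    }
  }
})

test_that("E-box density in uniform DNA matches (L-5)/256", {
  set.seed(85)
  L <- 200L
  n <- 400L
  counts <- vapply(seq_len(n), function(i) {
    seq <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    length(naiveIupacHits(seq, "CANNTG"))
  }, numeric(1))
  expected <- (L - 5) / 256
  se <- stats::sd(counts) / sqrt(n)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("per-gene summaries include zero-hit genes in the tally", {
  hits <- data.frame(gene_id = c("g1", "g1", "g2"),
                     element = c("E-box", "E-box", "G-box"),
                     position = c(3L, 40L, 7L), strand = "+",
                     match = c("CATGTG", "CACCTG", "CACGTG"))
  s <- summarizeElements(hits, c("g1", "g2", "g3"))
  expect_equal(s$n_with_hit, 2L)
  expect_equal(s$per_gene["g1", "E-box"], 2L)
  expect_equal(sum(s$per_gene["g3", ]), 0L)
  empty <- summarizeElements(hits[0, ], c("g1", "g2"))
  expect_equal(empty$n_with_hit, 0L)
})
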