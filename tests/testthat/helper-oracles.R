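# Independent oracles and small fixture builders used across the suite.

# base-resolution codon walk: assign each CDS base its position within the
# current codon; the phase of the intron after exon i is the codon offset
# of the first base of the next exon
codonWalkPhases <- function(exonLens) {
  k <- 0L
  phases <- integer(0)
  for (i in seq_along(exonLens)) {
    for (b in seq_len(exonLens[i])) k <- (k + 1L) %% 3L
    if (i < length(exonLens)) phases <- c(phases, k)
  }
  phases
}

# exhaustive affine-gap alignment score by plain recursion (no memoisation)
bruteForceAlignScore <- function(a, b, sub, open, ext) {
  A <- strsplit(a, "")[[1L]]
  B <- strsplit(b, "")[[1L]]
  rec <- function(i, j, prev) {
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B))
      best <- max(best, sub[A[i], B[j]] + rec(i + 1L, j + 1L, "M"))
    if (j <= length(B))
      best <- max(best, (if (prev == "Ia") ext else open + ext) +
                    rec(i, j + 1L, "Ia"))
    if (i <= length(A))
      best <- max(best, (if (prev == "Ib") ext else open + ext) +
                    rec(i + 1L, j, "Ib"))
    best
  }
  rec(1L, 1L, "")
}

# position-by-position IUPAC matcher, no regex, no Biostrings
naiveIupacHits <- function(seq, pattern) {
  map <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
              Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
              K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
              D = c("A", "G", "T"), H = c("A", "C", "T"),
              V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  s <- strsplit(seq, "")[[1L]]
  p <- strsplit(pattern, "")[[1L]]
  hits <- integer(0)
  if (length(s) < length(p)) return(hits)
  for (i in seq_len(length(s) - length(p) + 1L)) {
    ok <- TRUE
    for (k in seq_along(p)) {
      if (!s[i + k - 1L] %in% map[[p[k]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

# naive average-linkage agglomeration on a precomputed distance matrix,
# returning sorted merge heights
naiveAverageLinkHeights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestD <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i < j) {
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < bestD) { bestD <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, bestD)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  sort(heights)
}

# random exon-length vectors with total divisible by 3
randomExonLens <- function(maxExons = 8L) {
  k <- sample.int(maxExons, 1L)
  lens <- sample(1:300, k, replace = TRUE)
  rem <- sum(lens) %% 3L
  lens[k] <- lens[k] + (3L - rem) %% 3L
  lens
}

# tiny in-memory GeneModels builder: list of (contig, strand, starts, ends)
toyModels <- function(spec) {
  GeneModels(lapply(spec, function(g)
    GenomicRanges::GRanges(g$contig,
                           IRanges::IRanges(g$starts, g$ends),
                           strand = g$strand)))
}

writeTempFasta <- function(lines) {
  f <- tempfile(fileext = ".fa")
  writeLines(lines, f)
  f
}
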