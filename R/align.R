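# Gotoh affine-gap global alignment over abstract positions.
# scoreFun(i, j) scores pairing position i of "a" with position j of "b".
# A gap of length k costs open + k * extend (both negative).
# Traceback tie-break: match/mismatch > gap-in-a > gap-in-b.
gotohAlign <- function(scoreFun, n, m, open, extend) {
  NEG <- -1e18
  M <- matrix(NEG, n + 1L, m + 1L)
  Ia <- matrix(NEG, n + 1L, m + 1L)  # gap in a (consumes b)
  Ib <- matrix(NEG, n + 1L, m + 1L)  # gap in b (consumes a)
  M[1L, 1L] <- 0
  if (m > 0L) Ia[1L, 2L:(m + 1L)] <- open + extend * seq_len(m)
  if (n > 0L) Ib[2L:(n + 1L), 1L] <- open + extend * seq_len(n)
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      M[i, j] <- scoreFun(i - 1L, j - 1L) +
        max(M[i - 1L, j - 1L], Ia[i - 1L, j - 1L], Ib[i - 1L, j - 1L])
      Ia[i, j] <- max(M[i, j - 1L] + open + extend,
                      Ia[i, j - 1L] + extend,
                      Ib[i, j - 1L] + open + extend)
      Ib[i, j] <- max(M[i - 1L, j] + open + extend,
                      Ib[i - 1L, j] + extend,
                      Ia[i - 1L, j] + open + extend)
    }
  }
  score <- max(M[n + 1L, m + 1L], Ia[n + 1L, m + 1L], Ib[n + 1L, m + 1L])
  # traceback
  state <- c("M", "Ia", "Ib")[which.max(c(M[n + 1L, m + 1L],
                                          Ia[n + 1L, m + 1L],
                                          Ib[n + 1L, m + 1L]))]
  i <- n + 1L; j <- m + 1L
  ops <- character(0)
  eq <- function(x, y) abs(x - y) < 1e-9
  while (i > 1L || j > 1L) {
    if (state == "M") {
      ops <- c("M", ops)
      prev <- M[i - 1L, j - 1L] + scoreFun(i - 1L, j - 1L)
      state <- if (eq(M[i, j], prev)) "M"
      else if (eq(M[i, j], Ia[i - 1L, j - 1L] + scoreFun(i - 1L, j - 1L))) "Ia"
      else "Ib"
      i <- i - 1L; j <- j - 1L
    } else if (state == "Ia") {
      ops <- c("Ia", ops)
      cur <- Ia[i, j]
      state <- if (eq(cur, M[i, j - 1L] + open + extend)) "M"
      else if (eq(cur, Ia[i, j - 1L] + extend)) "Ia"
      else "Ib"
      j <- j - 1L
    } else {
      ops <- c("Ib", ops)
      cur <- Ib[i, j]
      state <- if (eq(cur, M[i - 1L, j] + open + extend)) "M"
      else if (eq(cur, Ib[i - 1L, j] + extend)) "Ib"
      else "Ia"
      i <- i - 1L
    }
  }
  list(score = score, ops = ops)
}

substMatrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Global pairwise protein alignment (Needleman-Wunsch, affine gaps)
#'
#' Maximises the substitution-matrix score with affine gap cost
#' `gapOpen + k * gapExtend` for a gap of length k.  Traceback ties are
#' broken deterministically: match/mismatch over gap-in-`a` over
#' gap-in-`b`.
#'
#' @param a,b protein sequences (character scalars).
#' @param substitution substitution matrix name in Biostrings (default
#'   `"BLOSUM62"`).
#' @param gapOpen,gapExtend gap penalties, negative (defaults -10, -1).
#' @return list with `a`, `b` (aligned strings with `-` gaps) and `score`.
#' @examples
#' alignPair("AAA", "AAA")$score  # 3 * BLOSUM62["A","A"] = 12
#' @export
alignPair <- function(a, b, substitution = "BLOSUM62",
                      gapOpen = -10, gapExtend = -1) {
  sub <- substMatrix(substitution)
  ca <- strsplit(toupper(a), "")[[1L]]
  cb <- strsplit(toupper(b), "")[[1L]]
  res <- gotohAlign(function(i, j) sub[ca[i], cb[j]],
                    length(ca), length(cb), gapOpen, gapExtend)
  ai <- 0L; bi <- 0L
  outA <- character(length(res$ops)); outB <- outA
  for (k in seq_along(res$ops)) {
    op <- res$ops[k]
    if (op == "M") {
      ai <- ai + 1L; bi <- bi + 1L
      outA[k] <- ca[ai]; outB[k] <- cb[bi]
    } else if (op == "Ia") {          # gap in a
      bi <- bi + 1L
      outA[k] <- "-"; outB[k] <- cb[bi]
    } else {                          # gap in b
      ai <- ai + 1L
      outA[k] <- ca[ai]; outB[k] <- "-"
    }
  }
  list(a = paste(outA, collapse = ""), b = paste(outB, collapse = ""),
       score = res$score)
}

# profile = character matrix (sequences x columns, "-" gaps)
profileColumnScore <- function(pa, pb, sub) {
  function(i, j) {
    ra <- pa[, i]; rb <- pb[, j]
    ra <- ra[ra != "-"]; rb <- rb[rb != "-"]
    if (length(ra) == 0L || length(rb) == 0L) return(0)
    mean(sub[ra, rb])
  }
}

mergeProfiles <- function(pa, pb, sub, gapOpen, gapExtend) {
  res <- gotohAlign(profileColumnScore(pa, pb, sub),
                    ncol(pa), ncol(pb), gapOpen, gapExtend)
  na <- nrow(pa); nb <- nrow(pb)
  out <- matrix("-", na + nb, length(res$ops))
  ai <- 0L; bi <- 0L
  for (k in seq_along(res$ops)) {
    op <- res$ops[k]
    if (op != "Ia") { ai <- ai + 1L; out[seq_len(na), k] <- pa[, ai] }
    if (op != "Ib") { bi <- bi + 1L; out[na + seq_len(nb), k] <- pb[, bi] }
  }
  rownames(out) <- c(rownames(pa), rownames(pb))
  out
}

kmerDistance <- function(seqs, k = 3L) {
  sets <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(s)
    unique(substring(s, seq_len(nchar(s) - k + 1L),
                     seq_len(nchar(s) - k + 1L) + k - 1L))
  })
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      shared <- length(intersect(sets[[i]], sets[[j]]))
      d[i, j] <- d[j, i] <-
        1 - shared / min(length(sets[[i]]), length(sets[[j]]))
    }
  }
  d
}

#' Progressive multiple alignment of domain sequences
#'
#' Builds a guide tree by average-linkage clustering of k-mer (k = 3)
#' distances and merges sequence profiles in guide-tree order with the
#' affine-gap profile aligner.  Two sequences reduce to [alignPair()].
#'
#' @param seqs a named `AAStringSet` or named character vector (>= 2
#'   sequences).
#' @inheritParams alignPair
#' @return a named character vector of equal-length aligned rows.
#' @export
progressiveAlign <- function(seqs, substitution = "BLOSUM62",
                             gapOpen = -10, gapExtend = -1) {
  seqs <- stats::setNames(toupper(as.character(seqs)), names(seqs))
  if (length(seqs) < 2L) stop("alignment input error: need >= 2 sequences")
  sub <- substMatrix(substitution)
  profiles <- lapply(names(seqs), function(nm) {
    m <- matrix(strsplit(seqs[[nm]], "")[[1L]], nrow = 1L)
    rownames(m) <- nm
    m
  })
  if (length(seqs) == 2L) {
    pw <- alignPair(seqs[[1L]], seqs[[2L]], substitution, gapOpen, gapExtend)
    out <- c(pw$a, pw$b)
    names(out) <- names(seqs)
    return(out)
  }
  d <- kmerDistance(seqs)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  # replay the merge sequence on profiles
  nodes <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    pick <- function(x) if (x < 0) profiles[[-x]] else nodes[[x]]
    nodes[[s]] <- mergeProfiles(pick(hc$merge[s, 1L]),
                                pick(hc$merge[s, 2L]),
                                sub, gapOpen, gapExtend)
  }
  final <- nodes[[length(nodes)]]
  out <- apply(final, 1L, paste, collapse = "")
  out[names(seqs)]
}
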