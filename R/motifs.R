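#' Scan proteins for motif occurrences (with repetitions)
#'
#' For each motif PSSM, every window scoring at least the motif's threshold
#' is a candidate occurrence; overlapping candidates are resolved greedily
#' in descending score order (the higher-scoring occurrence wins), so a
#' motif can legitimately occur several times in one protein.
#'
#' @param proteins a named `AAStringSet`.
#' @param motifs named list of [PSSM-class] objects (names = motif ids).
#' @param thresholds numeric vector of per-motif bit thresholds, recycled.
#' @return data.frame with `protein`, `motif`, `start`, `end`, `score`,
#'   sorted by protein, motif, start; occurrences never overlap within one
#'   protein x motif pair.
#' @export
scanMotifs <- function(proteins, motifs, thresholds) {
  stopifnot(!is.null(names(motifs)))
  thresholds <- rep_len(thresholds, length(motifs))
  rows <- list()
  for (pid in names(proteins)) {
    seq <- as.character(proteins[[pid]])
    chars <- strsplit(toupper(seq), "")[[1L]]
    col <- match(chars, AA20)
    for (mi in seq_along(motifs)) {
      pssm <- motifs[[mi]]
      L <- nrow(pssm@scores)
      if (length(chars) < L) next
      nW <- length(chars) - L + 1L
      winScores <- numeric(nW)
      for (p in seq_len(L)) {
        s <- pssm@scores[p, ]
        v <- s[col[p:(p + nW - 1L)]]
        v[is.na(v)] <- 0
        winScores <- winScores + v
      }
      cand <- which(winScores >= thresholds[mi])
      if (!length(cand)) next
      o <- cand[order(-winScores[cand], cand)]   # score desc, then start
      taken <- logical(length(chars))
      for (s0 in o) {
        span <- s0:(s0 + L - 1L)
        if (!any(taken[span])) {
          taken[span] <- TRUE
          rows[[length(rows) + 1L]] <- data.frame(
            protein = pid, motif = names(motifs)[mi],
            start = s0, end = s0 + L - 1L,
            score = winScores[s0])
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(protein = character(0), motif = character(0),
                      start = integer(0), end = integer(0),
                      score = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(out$protein, out$motif, out$start), , drop = FALSE]
}

#' Motif distribution by subfamily
#'
#' @param occurrences occurrence table from [scanMotifs()] (`protein` holds
#'   member names).
#' @param subfamilies named character vector: member name -> subfamily.
#' @return list with `presence` (subfamily x motif logical matrix) and
#'   `mean_count` (subfamily x motif mean occurrences per member).
#' @export
motifSubfamilyMatrix <- function(occurrences, subfamilies) {
  members <- names(subfamilies)
  if (nrow(occurrences) > 0 &&
      !all(occurrences$protein %in% members))
    stop("motif input error: occurrence protein(s) without subfamily label")
  sfs <- sort(unique(subfamilies))
  motifIds <- sort(unique(occurrences$motif))
  presence <- matrix(FALSE, length(sfs), length(motifIds),
                     dimnames = list(sfs, motifIds))
  meanCount <- matrix(0, length(sfs), length(motifIds),
                      dimnames = list(sfs, motifIds))
  for (m in motifIds) {
    occ <- occurrences[occurrences$motif == m, , drop = FALSE]
    perMember <- table(factor(occ$protein, levels = members))
    for (sf in sfs) {
      inSf <- subfamilies == sf
      presence[sf, m] <- any(perMember[inSf] > 0)
      meanCount[sf, m] <- mean(perMember[inSf])
    }
  }
  list(presence = presence, mean_count = meanCount)
}

#' Read / write motif PSSM sets as TSV
#'
#' Long format: columns `motif`, `position`, then one column per residue
#' (the 20 standard amino acids) holding bit scores.
#'
#' @param path TSV path.
#' @param background background frequencies for the reconstructed PSSMs.
#' @return `readMotifSet`: named list of [PSSM-class]; `writeMotifSet`:
#'   `path`, invisibly.
#' @export
readMotifSet <- function(path, background = rep(1 / 20, 20)) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!all(c("motif", "position", AA20) %in% colnames(df)))
    stop("motif table format error: need motif, position and 20 residue columns")
  names(background) <- AA20
  out <- lapply(split(df, df$motif), function(sub) {
    sub <- sub[order(sub$position), , drop = FALSE]
    m <- as.matrix(sub[, AA20])
    rownames(m) <- as.character(seq_len(nrow(m)))
    new("PSSM", scores = m, background = background)
  })
  out
}

#' @rdname readMotifSet
#' @param motifs named list of [PSSM-class] objects.
#' @export
writeMotifSet <- function(motifs, path) {
  rows <- lapply(names(motifs), function(id) {
    m <- motifs[[id]]@scores
    data.frame(motif = id, position = seq_len(nrow(m)), m,
               check.names = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
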