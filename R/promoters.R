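#' Extract promoter regions upstream of the translation start
#'
#' For a `+` strand gene whose first CDS base is at position `s`, the
#' promoter is the contig interval `[s - length, s - 1]`; for a `-` strand
#' gene ending at `e` it is the reverse complement of `[e + 1, e + length]`
#' — in both cases the transcription-strand sequence immediately 5' of the
#' first coding base.  Regions running off the contig are truncated and
#' flagged; a gene flush against the contig edge yields an empty promoter
#' with the flag set, not an error.
#'
#' @param genome a named `DNAStringSet` of contigs.
#' @param models a [GeneModels-class] object.
#' @param length requested promoter length, bp (default 1500).
#' @return data.frame with `gene_id`, `contig`, `strand`, `sequence`,
#'   `length` (actual) and `truncated`.
#' @export
extractPromoters <- function(genome, models, length = 1500L) {
  grl <- cdsBy(models)
  rows <- lapply(names(grl), function(g) {
    gr <- grl[[g]]
    contigId <- as.character(seqnames(gr))[1L]
    if (!contigId %in% names(genome))
      stop("promoter input error: contig '", contigId, "' not in genome")
    contig <- genome[[contigId]]
    st <- as.character(strand(gr))[1L]
    if (st == "+") {
      s <- min(start(gr))
      lo <- max(1L, s - length); hi <- s - 1L
    } else {
      e <- max(end(gr))
      lo <- e + 1L; hi <- min(Biostrings::nchar(contig), e + length)
    }
    seq <- if (hi < lo) "" else
      as.character(Biostrings::subseq(contig, lo, hi))
    if (st == "-" && nchar(seq))
      seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq)))
    data.frame(gene_id = g, contig = contigId, strand = st,
               sequence = seq, length = nchar(seq),
               truncated = nchar(seq) < length)
  })
  do.call(rbind, rows)
}

IUPAC_MAP <- c(A = "A", C = "C", G = "G", T = "T",
               R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
               B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

iupacMatchesAt <- function(chars, pattern, pos) {
  pat <- strsplit(pattern, "")[[1L]]
  all(vapply(seq_along(pat), function(k) {
    ch <- chars[pos + k - 1L]
    !is.na(ch) && grepl(ch, IUPAC_MAP[[pat[k]]], fixed = TRUE)
  }, logical(1)))
}

revCompIupac <- function(pattern) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(pattern, "")[[1L]]]), collapse = "")
}

#' Scan promoters for IUPAC cis-elements
#'
#' Reports every position where the pattern matches; with
#' `bothStrands = TRUE` the reverse complement of the pattern is scanned
#' too (hit positions on the forward coordinate system, strand recorded).
#' A palindromic pattern — equal to its own reverse complement, like the
#' E-box CANNTG — is scanned on the forward strand only, so each site is
#' reported once.
#'
#' @param promoters data.frame from [extractPromoters()] (needs `gene_id`
#'   and `sequence`).
#' @param elements data.frame from [readElements()] (`name`, `pattern`).
#' @param bothStrands scan the reverse complement too (default TRUE).
#' @return data.frame with `gene_id`, `element`, `position` (1-based on
#'   the promoter), `strand`, `match`.
#' @export
scanElements <- function(promoters, elements, bothStrands = TRUE) {
  bad <- !grepl("^[ACGTRYSWKMBDHVN]+$", toupper(elements$pattern))
  if (any(bad))
    stop("element config error: invalid IUPAC pattern '",
         elements$pattern[bad][1L], "'")
  rows <- list()
  for (gi in seq_len(nrow(promoters))) {
    seq <- toupper(promoters$sequence[gi])
    if (!nchar(seq)) next
    subject <- Biostrings::DNAString(seq)
    for (ei in seq_len(nrow(elements))) {
      pat <- toupper(elements$pattern[ei])
      palindromic <- identical(pat, revCompIupac(pat))
      strands <- if (bothStrands && !palindromic) c("+", "-") else "+"
      for (std in strands) {
        p <- if (std == "+") pat else revCompIupac(pat)
        if (nchar(p) > nchar(seq)) next
        hits <- Biostrings::matchPattern(p, subject, fixed = FALSE)
        if (length(hits) == 0L) next
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = promoters$gene_id[gi],
          element = elements$name[ei],
          position = Biostrings::start(hits),
          strand = std,
          match = as.character(hits))
      }
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(0), element = character(0),
                      position = integer(0), strand = character(0),
                      match = character(0)))
  out <- do.call(rbind, rows)
  out[order(out$gene_id, out$element, out$position, out$strand), ,
      drop = FALSE]
}

#' Summarise element hits per gene
#'
#' @param hits data.frame from [scanElements()].
#' @param universe character vector of gene ids the tally is taken over
#'   (zero-hit genes included).
#' @return list with `per_gene` (gene x element count matrix over the
#'   universe) and `n_with_hit` (genes with >= 1 hit of any element).
#' @export
summarizeElements <- function(hits, universe) {
  els <- sort(unique(hits$element))
  counts <- matrix(0L, length(universe), max(1L, length(els)),
                   dimnames = list(universe,
                                   if (length(els)) els else "none"))
  if (nrow(hits)) {
    tab <- table(factor(hits$gene_id, levels = universe),
                 factor(hits$element, levels = els))
    counts <- matrix(as.integer(tab), nrow = length(universe),
                     dimnames = dimnames(tab))
  }
  list(per_gene = counts, n_with_hit = sum(rowSums(counts) > 0))
}
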