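#' Build a PSSM from a seed alignment
#'
#' Column residue counts plus a pseudocount give per-position frequencies,
#' which are converted to log2 odds against the background.  Columns with
#' more than 50% gaps are dropped.
#'
#' @param seedAlignment an aligned `AAStringSet` (equal widths, `-` gaps),
#'   at least 2 sequences.
#' @param pseudocount positive real added to each residue count (default 1).
#' @param background 20 background frequencies named by residue (default
#'   uniform 1/20).
#' @return a [PSSM-class] object.
#' @examples
#' aln <- Biostrings::AAStringSet(c(s1 = "AC", s2 = "AC"))
#' p <- buildPssm(aln)
#' p@scores["1", "A"]  # log2((2+1)/(2+20) / 0.05)
#' @export
buildPssm <- function(seedAlignment, pseudocount = 1,
                      background = rep(1 / 20, 20)) {
  if (length(seedAlignment) < 2L)
    stop("PSSM input error: need at least 2 aligned sequences")
  w <- unique(Biostrings::width(seedAlignment))
  if (length(w) != 1L)
    stop("PSSM input error: aligned sequences must have equal length")
  if (pseudocount <= 0) stop("PSSM input error: pseudocount must be positive")
  names(background) <- AA20
  chars <- do.call(rbind, strsplit(as.character(seedAlignment), ""))
  keep <- colMeans(chars == "-") <= 0.5
  if (!any(keep)) stop("PSSM input error: all columns are majority-gap")
  chars <- chars[, keep, drop = FALSE]
  n <- nrow(chars)
  scores <- t(apply(chars, 2L, function(col) {
    col <- col[col != "-"]
    counts <- table(factor(col, levels = AA20))
    freq <- (as.numeric(counts) + pseudocount) /
      (length(col) + 20 * pseudocount)
    log2(freq / background)
  }))
  colnames(scores) <- AA20
  rownames(scores) <- as.character(seq_len(nrow(scores)))
  new("PSSM", scores = scores, background = background)
}

#' Per-position residue probabilities implied by a PSSM
#'
#' Inverts the log-odds transform: `p = background * 2^score`, renormalised
#' per position.  Used to sample representative domain sequences.
#'
#' @param pssm a [PSSM-class] object.
#' @return positions x 20 probability matrix.
#' @export
pssmProfile <- function(pssm) {
  p <- sweep(2^pssm@scores, 2L, pssm@background, `*`)
  p / rowSums(p)
}

#' Scan a protein for the best-scoring PSSM window
#'
#' Slides a window of the PSSM width along the sequence and returns the
#' maximal-score window; ties are broken toward the smallest start.
#' Non-standard residues score 0 bits (background) and are reported in the
#' `n_unknown` field.
#'
#' @param pssm a [PSSM-class] object.
#' @param protein a protein sequence (character scalar or `AAString`).
#' @return a list with `start`, `end` (1-based closed), `score` (bits) and
#'   `n_unknown`, or `NULL` when the protein is shorter than the PSSM.
#' @export
scanProtein <- function(pssm, protein) {
  seq <- toupper(as.character(protein))
  L <- nrow(pssm@scores)
  chars <- strsplit(seq, "")[[1L]]
  n <- length(chars)
  if (n < L) return(NULL)
  col <- match(chars, AA20)          # NA for unknown residues -> 0 bits
  nW <- n - L + 1L
  winScores <- numeric(nW)
  for (p in seq_len(L)) {
    s <- pssm@scores[p, ]
    v <- s[col[p:(p + nW - 1L)]]
    v[is.na(v)] <- 0
    winScores <- winScores + v
  }
  # smallest start among (epsilon-tied) maxima
  best <- which(winScores >= max(winScores) - 1e-9)[1L]
  list(start = unname(best), end = unname(best) + L - 1L,
       score = unname(winScores[best]), n_unknown = sum(is.na(col)))
}

#' Choose a PSSM score threshold by Youden's J on model-implied score
#' distributions
#'
#' Positive scores are drawn by sampling domain sequences from the PSSM's
#' own per-position profile and scoring them; negative scores are the
#' *best-window* scores of random background proteins (the statistic the
#' classifier actually thresholds: a maximum over all windows).  The
#' returned threshold maximises J = TPR - FPR over the pooled score grid
#' (smallest such value on ties), so it needs no labelled data and is
#' deterministic given the seed.
#'
#' @param pssm a [PSSM-class] object.
#' @param n samples per class (default 300).
#' @param bgLength background protein length for the negatives
#'   (default 300).
#' @param seed RNG seed (default 1).
#' @return threshold in bits.
#' @export
choosePssmThreshold <- function(pssm, n = 300L, bgLength = 300L, seed = 1L) {
  prof <- pssmProfile(pssm)
  L <- nrow(prof)
  scoreOf <- function(idx) sum(pssm@scores[cbind(seq_len(L), idx)])
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  pos <- vapply(seq_len(n), function(i) {
    scoreOf(apply(prof, 1L, function(p) sample.int(20L, 1L, prob = p)))
  }, numeric(1))
  neg <- vapply(seq_len(n), function(i) {
    seq <- paste(sample(AA20, bgLength, replace = TRUE,
                        prob = pssm@background), collapse = "")
    scanProtein(pssm, seq)$score
  }, numeric(1))
  grid <- sort(unique(c(pos, neg)))
  J <- vapply(grid, function(t) mean(pos >= t) - mean(neg >= t), numeric(1))
  grid[which.max(J)]
}

#' Splice cDNA sequences from a genome and gene models
#'
#' Concatenates each gene's CDS segments in transcription order; minus-strand
#' genes are reverse-complemented.
#'
#' @param genome a named `DNAStringSet` of contigs.
#' @param models a [GeneModels-class] object.
#' @return a `DNAStringSet` of cDNA (CDS) sequences named by gene id.
#' @export
spliceCds <- function(genome, models) {
  grl <- cdsBy(models)
  out <- vapply(names(grl), function(g) {
    gr <- grl[[g]]
    contig <- genome[[as.character(seqnames(gr))[1L]]]
    segs <- lapply(order(start(gr)), function(i)
      Biostrings::subseq(contig, start(gr)[i], end(gr)[i]))
    cdna <- do.call(Biostrings::xscat, segs)
    if (as.character(strand(gr))[1L] == "-")
      cdna <- Biostrings::reverseComplement(cdna)
    as.character(cdna)
  }, character(1))
  Biostrings::DNAStringSet(out)
}

#' Validate an open reading frame
#'
#' A CDS is a valid ORF iff its length is divisible by 3, it starts with
#' ATG, ends with a stop codon (TAA/TAG/TGA) and contains no internal stop.
#'
#' @param cds a DNA sequence (character scalar or `DNAString`).
#' @return list with `ok` (logical) and `reason` (character, `""` if ok).
#' @examples
#' validateOrf("ATGGCCTAA")$ok     # TRUE
#' validateOrf("ATGTAATAA")$reason # internal stop
#' @export
validateOrf <- function(cds) {
  seq <- toupper(as.character(cds))
  if (nchar(seq) == 0L) return(list(ok = FALSE, reason = "empty sequence"))
  if (grepl("[^ACGT]", seq))
    return(list(ok = FALSE, reason = "ambiguous base"))
  if (nchar(seq) %% 3L != 0L)
    return(list(ok = FALSE, reason = "length not divisible by 3"))
  codons <- substring(seq, seq(1L, nchar(seq) - 2L, by = 3L),
                      seq(3L, nchar(seq), by = 3L))
  stops <- c("TAA", "TAG", "TGA")
  if (codons[1L] != "ATG") return(list(ok = FALSE, reason = "no ATG start"))
  if (!codons[length(codons)] %in% stops)
    return(list(ok = FALSE, reason = "no terminal stop"))
  if (any(codons[-length(codons)] %in% stops))
    return(list(ok = FALSE, reason = "internal stop"))
  list(ok = TRUE, reason = "")
}

#' Identify family members by PSSM domain scan with ORF validation
#'
#' A protein joins the family when its best PSSM window scores at least
#' `thresholdBits` and its CDS (spliced from `genome`) is a valid ORF.
#' Members are named `prefix` + ordinal in ascending gene-coordinate order
#' (contig id, then transcription start), independent of input order.
#' Proteins without a gene model are excluded with a warning.
#'
#' @param proteome a named `AAStringSet`; ids must match gene ids in
#'   `models`.
#' @param models a [GeneModels-class] object.
#' @param pssm a [PSSM-class] object.
#' @param genome optional named `DNAStringSet`; when supplied, ORF
#'   validation is performed on the spliced CDS (skipped otherwise).
#' @param thresholdBits bit-score cutoff; `NULL` (default) uses
#'   [choosePssmThreshold()].
#' @param prefix member-name prefix (default `"bHLH"`).
#' @return a `DataFrame` with one row per member: `name`, `gene_id`,
#'   `domain_start`, `domain_end`, `score`, `gene_length`, `cdna_length`,
#'   `protein_length`, sorted in naming order.  The threshold used is in
#'   `metadata()$threshold_bits`.
#' @export
identifyFamily <- function(proteome, models, pssm, genome = NULL,
                           thresholdBits = NULL, prefix = "bHLH") {
  if (is.null(thresholdBits)) thresholdBits <- choosePssmThreshold(pssm)
  known <- names(proteome) %in% geneIds(models)
  if (any(!known)) {
    warning("excluding ", sum(!known),
            " protein(s) without a gene model: ",
            paste(utils::head(names(proteome)[!known], 3L), collapse = ", "))
    proteome <- proteome[known]
  }
  if (!is.null(genome)) cdna <- spliceCds(genome, models)
  hits <- lapply(names(proteome), function(id) {
    h <- scanProtein(pssm, proteome[[id]])
    if (is.null(h) || h$score < thresholdBits) return(NULL)
    if (!is.null(genome) && !validateOrf(cdna[[id]])$ok) return(NULL)
    c(list(gene_id = id), h[c("start", "end", "score")])
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (length(hits) == 0L) {
    out <- S4Vectors::DataFrame(name = character(0), gene_id = character(0),
                                domain_start = integer(0),
                                domain_end = integer(0), score = numeric(0),
                                gene_length = integer(0),
                                cdna_length = integer(0),
                                protein_length = integer(0))
    S4Vectors::metadata(out)$threshold_bits <- thresholdBits
    return(out)
  }
  ids <- vapply(hits, `[[`, character(1), "gene_id")
  contig <- geneContig(models)[ids]
  startPos <- vapply(cdsBy(models)[ids], function(gr) min(start(gr)),
                     integer(1))
  o <- order(contig, startPos, ids)
  hits <- hits[o]; ids <- ids[o]
  out <- S4Vectors::DataFrame(
    name = paste0(prefix, seq_along(hits)),
    gene_id = ids,
    domain_start = vapply(hits, `[[`, numeric(1), "start"),
    domain_end = vapply(hits, `[[`, numeric(1), "end"),
    score = vapply(hits, `[[`, numeric(1), "score"),
    gene_length = unname(geneSpan(models)[ids]),
    cdna_length = unname(cdsLengths(models)[ids]),
    protein_length = unname(Biostrings::width(proteome)[match(ids, names(proteome))]))
  S4Vectors::metadata(out)$threshold_bits <- thresholdBits
  out
}
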