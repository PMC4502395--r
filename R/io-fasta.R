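#' Read a FASTA file into a Biostrings set
#'
#' Headers are split at the first whitespace: the leading token becomes the
#' record id, the remainder is kept as the `description` metadata column.
#' Sequences are upper-cased.  Duplicate ids and empty sequences are format
#' errors.
#'
#' @param path FASTA file path.
#' @param type `"DNA"`, `"AA"` or `"B"` (uninterpreted); controls the
#'   returned `XStringSet` flavour and alphabet checking.
#' @return a [Biostrings::DNAStringSet], [Biostrings::AAStringSet] or
#'   [Biostrings::BStringSet], named by id, with a `description` column in
#'   `mcols()`.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">g1 demo", "AC", "GT"), f)
#' readFasta(f, "DNA")
#' @export
readFasta <- function(path, type = c("DNA", "AA", "B")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("FASTA format error: no records in ", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("FASTA format error: duplicate id '",
         ids[duplicated(ids)][1L], "' in ", path)
  if (any(Biostrings::width(raw) == 0L))
    stop("FASTA format error: empty sequence for id '",
         ids[Biostrings::width(raw) == 0L][1L], "'")
  seqs <- toupper(as.character(raw))
  out <- switch(type,
                DNA = Biostrings::DNAStringSet(seqs),
                AA  = Biostrings::AAStringSet(seqs),
                B   = Biostrings::BStringSet(seqs))
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc)
  out
}

#' Write sequences as FASTA
#'
#' @param x a named `XStringSet` (or named character vector).
#' @param path output path.
#' @param width line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path, width = 70L) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  stopifnot(!is.null(names(x)))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}
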