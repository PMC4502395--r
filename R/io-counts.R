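CONDITION_LEVELS <- c("flower", "leaf", "root", "stem",
                      "periderm", "phloem", "xylem", "T0", "T12")

#' Read a gene x library count matrix with library metadata
#'
#' The matrix TSV has gene ids in the first column and one column per
#' library; the metadata TSV has columns `library_id`, `condition`,
#' `replicate`, `total_mapped`.  Matrix columns are matched to metadata
#' rows by library id, order-independently.  Counts must be non-negative
#' integers; condition labels must come from the declared vocabulary
#' (flower, leaf, root, stem, periderm, phloem, xylem, T0, T12).
#'
#' @param path counts TSV path.
#' @param metaPath library-metadata TSV path.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts` and the metadata as `colData`.
#' @export
readCounts <- function(path, metaPath) {
  mat <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(mat) < 2L) stop("count format error: need gene id + >=1 library")
  genes <- as.character(mat[[1L]])
  m <- as.matrix(mat[, -1L, drop = FALSE])
  meta <- utils::read.delim(metaPath, stringsAsFactors = FALSE)
  needed <- c("library_id", "condition", "replicate", "total_mapped")
  if (!all(needed %in% colnames(meta)))
    stop("metadata format error: missing column(s) ",
         paste(setdiff(needed, colnames(meta)), collapse = ", "))
  makeCountMatrix(m, genes, meta)
}

# shared validation for file-read and in-memory count tables
makeCountMatrix <- function(m, genes, meta) {
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("count format error: missing values in count matrix")
  if (any(m < 0)) stop("count format error: negative count")
  if (any(m != floor(m))) stop("count format error: non-integer count")
  storage.mode(m) <- "integer"
  if (anyDuplicated(genes)) stop("count format error: duplicate gene id")
  rownames(m) <- genes
  missing <- setdiff(colnames(m), meta$library_id)
  if (length(missing))
    stop("count format error: library '", missing[1L],
         "' absent from metadata")
  meta <- meta[match(colnames(m), meta$library_id), , drop = FALSE]
  if (!all(meta$condition %in% CONDITION_LEVELS))
    stop("metadata format error: unknown condition '",
         setdiff(meta$condition, CONDITION_LEVELS)[1L], "'")
  if (any(meta$total_mapped <= 0))
    stop("metadata format error: total_mapped must be positive")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(meta, row.names = meta$library_id))
}

#' Write a count table and its metadata as TSVs
#'
#' @param se a `SummarizedExperiment` from [readCounts()] or
#'   [simulateCounts()].
#' @param path counts TSV path.
#' @param metaPath metadata TSV path.
#' @return `path`, invisibly.
#' @export
writeCounts <- function(se, path, metaPath) {
  m <- SummarizedExperiment::assay(se, "counts")
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(SummarizedExperiment::colData(se)),
                     metaPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cis-element table (name, IUPAC pattern, description)
#'
#' @param path TSV with columns `name`, `pattern`, `description` (the last
#'   optional).
#' @return a data.frame with validated IUPAC patterns.
#' @export
readElements <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "pattern") %in% colnames(df)))
    stop("element table format error: need columns name, pattern")
  if (!"description" %in% colnames(df)) df$description <- ""
  bad <- !grepl("^[ACGTRYSWKMBDHVN]+$", toupper(df$pattern))
  if (any(bad))
    stop("element table format error: invalid IUPAC pattern '",
         df$pattern[bad][1L], "'")
  df$pattern <- toupper(df$pattern)
  df[, c("name", "pattern", "description")]
}
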