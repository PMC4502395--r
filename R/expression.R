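#' RPKM normalisation of a count table
#'
#' `RPKM = 1e9 * C / (N * L)` with `C` the gene's read count in a library,
#' `N` the library's total mapped reads (from the metadata, not the column
#' sum) and `L` the gene's cDNA length in bp.
#'
#' @param counts a `SummarizedExperiment` from [readCounts()] /
#'   [simulateCounts()].
#' @param lengths named numeric vector: gene id -> cDNA length (bp).
#' @return a `SummarizedExperiment` with assay `rpkm`, the same `colData`,
#'   and `length_bp` in `rowData`.
#' @examples
#' # C = 10, N = 1e6, L = 1000  ->  RPKM 10
#' @export
computeRpkm <- function(counts, lengths) {
  m <- SummarizedExperiment::assay(counts, "counts")
  missing <- setdiff(rownames(m), names(lengths))
  if (length(missing))
    stop("RPKM input error: no cDNA length for gene '", missing[1L], "'")
  L <- lengths[rownames(m)]
  if (any(L <= 0)) stop("RPKM input error: non-positive cDNA length")
  N <- SummarizedExperiment::colData(counts)$total_mapped
  rpkm <- 1e9 * sweep(sweep(m, 2L, N, `/`), 1L, L, `/`)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(rpkm = rpkm),
    colData = SummarizedExperiment::colData(counts),
    rowData = S4Vectors::DataFrame(length_bp = unname(L)))
}

#' Average replicate libraries into condition-level RPKM
#'
#' Arithmetic mean of replicate RPKM values per condition; single-replicate
#' conditions pass through unchanged.  Replicate order does not matter.
#'
#' @param rpkm a `SummarizedExperiment` with assay `rpkm` and `condition`
#'   in `colData`.
#' @return a `SummarizedExperiment` with one column per condition.
#' @export
aggregateReplicates <- function(rpkm) {
  m <- SummarizedExperiment::assay(rpkm, "rpkm")
  cond <- as.character(SummarizedExperiment::colData(rpkm)$condition)
  lv <- unique(cond)
  agg <- matrix(0, nrow(m), length(lv),
                dimnames = list(rownames(m), lv))
  for (cv in lv) agg[, cv] <- rowMeans(m[, cond == cv, drop = FALSE])
  SummarizedExperiment::SummarizedExperiment(
    assays = list(rpkm = agg),
    colData = S4Vectors::DataFrame(condition = lv, row.names = lv),
    rowData = SummarizedExperiment::rowData(rpkm))
}

#' Detection and condition-specific expression calls
#'
#' A gene is *detected* in a condition when its RPKM exceeds 0, and
#' *specific* to a condition when it is detected there and has RPKM exactly
#' 0 in every other condition of the group — no minimum level is applied,
#' so very low specific expression still counts.
#'
#' @param condRpkm condition-level `SummarizedExperiment` from
#'   [aggregateReplicates()].
#' @param group condition names forming the comparison group (e.g.
#'   `c("flower","leaf","root","stem")`).
#' @return data.frame with `gene_id`, `detected_in` (comma string),
#'   `n_detected`, `specific_to` (`NA` if none).
#' @export
detectionAndSpecificity <- function(condRpkm,
                                    group = c("flower", "leaf",
                                              "root", "stem")) {
  m <- SummarizedExperiment::assay(condRpkm, "rpkm")
  if (!all(group %in% colnames(m)))
    stop("expression input error: missing condition(s) ",
         paste(setdiff(group, colnames(m)), collapse = ", "))
  m <- m[, group, drop = FALSE]
  det <- m > 0
  specific <- apply(det, 1L, function(r)
    if (sum(r) == 1L) group[r] else NA_character_)
  data.frame(
    gene_id = rownames(m),
    detected_in = apply(det, 1L, function(r) paste(group[r], collapse = ",")),
    n_detected = rowSums(det),
    specific_to = specific,
    row.names = NULL)
}

#' Fold-enrichment filter
#'
#' A gene passes for the target condition when its RPKM there exceeds
#' `minRpkm` and is at least `fold` times the RPKM of *every* other
#' condition in `others`.  The fold comparison uses `>=`.
#'
#' @inheritParams detectionAndSpecificity
#' @param target target condition.
#' @param others conditions to dominate.
#' @param fold fold requirement (default 2).
#' @param minRpkm minimum target RPKM, strict (default 1).
#' @return character vector of passing gene ids.
#' @export
enrichmentFilter <- function(condRpkm, target, others, fold = 2,
                             minRpkm = 1) {
  stopifnot(!target %in% others)
  m <- SummarizedExperiment::assay(condRpkm, "rpkm")
  if (!all(c(target, others) %in% colnames(m)))
    stop("expression input error: missing condition(s) ",
         paste(setdiff(c(target, others), colnames(m)), collapse = ", "))
  tv <- m[, target]
  ok <- tv > minRpkm
  for (o in others) ok <- ok & (tv >= fold * m[, o])
  rownames(m)[ok]
}

#' MeJA up-regulation call
#'
#' Up-regulated iff `(RPKM(t12) + pseudocount) / (RPKM(t0) + pseudocount)
#' >= fold` and `RPKM(t12) > minRpkm`.  The pseudocount keeps zero
#' baselines comparable.
#'
#' @param rpkm a `SummarizedExperiment` with assay `rpkm` (library- or
#'   condition-level).
#' @param t0,t12 column names of the control and treated libraries.
#' @param fold fold requirement (default 2).
#' @param minRpkm minimum treated RPKM, strict (default 1).
#' @param pseudocount added to both sides of the ratio (default 0.1).
#' @return character vector of up-regulated gene ids.
#' @export
mejaResponse <- function(rpkm, t0 = "T0", t12 = "T12", fold = 2,
                         minRpkm = 1, pseudocount = 0.1) {
  m <- SummarizedExperiment::assay(rpkm, "rpkm")
  if (!all(c(t0, t12) %in% colnames(m)))
    stop("expression input error: libraries ", t0, "/", t12, " not found")
  ratio <- (m[, t12] + pseudocount) / (m[, t0] + pseudocount)
  rownames(m)[ratio >= fold & m[, t12] > minRpkm]
}

#' Hierarchical clustering of expression profiles
#'
#' Profiles are transformed `log2(RPKM + 1)`, a gene-gene distance is
#' computed (`correlation` = 1 - Pearson r across conditions, or
#' `euclidean`), and agglomerative clustering (average or complete
#' linkage) returns the merge tree and heatmap leaf order.  A gene with
#' zero variance has no defined correlation; it is assigned distance 1 to
#' every other gene and reported in `zero_variance`.
#'
#' @param condRpkm condition-level `SummarizedExperiment`.
#' @param distance `"correlation"` (default) or `"euclidean"`.
#' @param linkage `"average"` (default) or `"complete"`.
#' @return list with `hclust` (the [stats::hclust] object), `order`
#'   (gene ids in leaf order), `height` (merge heights) and
#'   `zero_variance` (gene ids, possibly empty).
#' @export
hierarchicalCluster <- function(condRpkm,
                                distance = c("correlation", "euclidean"),
                                linkage = c("average", "complete")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  m <- log2(SummarizedExperiment::assay(condRpkm, "rpkm") + 1)
  if (nrow(m) < 2L) stop("clustering input error: need >= 2 genes")
  zeroVar <- apply(m, 1L, stats::sd) == 0
  if (distance == "correlation") {
    d <- matrix(1, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
    ok <- which(!zeroVar)
    if (length(ok) >= 2L) {
      cc <- stats::cor(t(m[ok, , drop = FALSE]))
      d[ok, ok] <- 1 - cc
    }
    diag(d) <- 0
    dd <- stats::as.dist(d)
  } else {
    dd <- stats::dist(m)
  }
  hc <- stats::hclust(dd, method = linkage)
  list(hclust = hc, order = rownames(m)[hc$order], height = hc$height,
       zero_variance = rownames(m)[zeroVar])
}
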