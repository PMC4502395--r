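#' Intron phases of a gene model
#'
#' The phase of intron *i* is the cumulative CDS length of the exons 5' of
#' it, modulo 3: phase 0 introns fall between codons, phase 1/2 after the
#' first/second codon base.  The total CDS length must be divisible by 3.
#'
#' @param exonLens integer vector of CDS-segment lengths in transcription
#'   order (bp).
#' @return integer vector of length `length(exonLens) - 1` over \{0,1,2\}.
#' @examples
#' intronPhases(c(100, 200, 66))  # 1, 0
#' @export
intronPhases <- function(exonLens) {
  exonLens <- as.integer(exonLens)
  if (sum(exonLens) %% 3L != 0L)
    stop("structure error: CDS length ", sum(exonLens),
         " not divisible by 3")
  n <- length(exonLens)
  if (n == 1L) return(integer(0))
  cumsum(exonLens)[-n] %% 3L
}

#' Per-exon boundary phases and symmetry classification
#'
#' An exon is *symmetric* when its 5' and 3' boundary phases are equal.
#' Internal exons take the phases of their flanking introns.  Terminal
#' exons have only one flanking intron; the `policy` decides their fate:
#' `"terminal_virtual_zero"` assigns a virtual phase 0 to the missing
#' boundary (first exon 5' = 0, last exon 3' = 0), `"internal_only"` never
#' marks terminal exons symmetric.  Single-exon genes are never symmetric
#' under either policy.
#'
#' @param exonLens CDS-segment lengths in transcription order (bp).
#' @param policy `"terminal_virtual_zero"` (default) or `"internal_only"`.
#' @return data.frame with `phase5`, `phase3` (NA where undefined under
#'   `internal_only`) and `symmetric` per exon.
#' @export
classifySymmetric <- function(exonLens,
                              policy = c("terminal_virtual_zero",
                                         "internal_only")) {
  policy <- match.arg(policy)
  ph <- intronPhases(exonLens)
  n <- length(exonLens)
  p5 <- c(NA_integer_, ph)          # 5' boundary phase per exon
  p3 <- c(ph, NA_integer_)          # 3' boundary phase per exon
  if (policy == "terminal_virtual_zero") {
    p5[1L] <- 0L
    p3[n] <- 0L
  }
  sym <- !is.na(p5) & !is.na(p3) & p5 == p3
  if (n == 1L) sym[] <- FALSE
  data.frame(phase5 = p5, phase3 = p3, symmetric = sym)
}

#' Family-wide exon/intron architecture summary
#'
#' Aggregates intron-phase and symmetric-exon statistics over a member set:
#' total exons and introns, the intron-phase histogram, symmetric-exon
#' counts by shared phase, the intronless gene list, and per-subfamily
#' mean exon counts (unrounded and rounded).
#'
#' @param members member table from [identifyFamily()].
#' @param models a [GeneModels-class] object covering every member.
#' @param subfamilies optional named character vector (member name ->
#'   subfamily label) from [assignSubfamilies()].
#' @param policy passed to [classifySymmetric()].
#' @return list with `per_gene` (data.frame: name, exon count, intronless,
#'   phases as comma string, symmetric exon count), `total_exons`,
#'   `total_introns`, `phase_histogram` (named 0/1/2),
#'   `symmetric_by_phase` (named 0/1/2), `intronless` (member names), and,
#'   when subfamilies are given, `subfamily_mean_exons` (data.frame with
#'   unrounded and rounded means).
#' @export
summarizeStructures <- function(members, models, subfamilies = NULL,
                                policy = "terminal_virtual_zero") {
  lens <- exonLengths(models)
  perGene <- lapply(seq_len(nrow(members)), function(i) {
    id <- members$gene_id[i]
    if (!id %in% names(lens))
      stop("structure error: no gene model for member ", members$name[i])
    el <- lens[[id]]
    ph <- tryCatch(intronPhases(el), error = function(e)
      stop("structure error in gene '", id, "': ", conditionMessage(e)))
    cs <- classifySymmetric(el, policy)
    list(name = members$name[i], gene_id = id, n_exons = length(el),
         phases = ph, sym = cs)
  })
  allPhases <- unlist(lapply(perGene, `[[`, "phases"))
  phaseHist <- table(factor(allPhases, levels = 0:2))
  symPhase <- unlist(lapply(perGene, function(g) {
    with(g$sym, phase5[symmetric])
  }))
  symHist <- table(factor(symPhase, levels = 0:2))
  perGeneDf <- data.frame(
    name = vapply(perGene, `[[`, character(1), "name"),
    gene_id = vapply(perGene, `[[`, character(1), "gene_id"),
    n_exons = vapply(perGene, `[[`, integer(1), "n_exons"),
    intronless = vapply(perGene, function(g) g$n_exons == 1L, logical(1)),
    phases = vapply(perGene, function(g)
      paste(g$phases, collapse = ","), character(1)),
    n_symmetric = vapply(perGene, function(g) sum(g$sym$symmetric),
                         integer(1)))
  out <- list(per_gene = perGeneDf,
              total_exons = sum(perGeneDf$n_exons),
              total_introns = sum(perGeneDf$n_exons - 1L),
              phase_histogram = stats::setNames(as.integer(phaseHist), 0:2),
              symmetric_by_phase = stats::setNames(as.integer(symHist), 0:2),
              intronless = perGeneDf$name[perGeneDf$intronless],
              policy = policy)
  if (!is.null(subfamilies)) {
    sf <- subfamilies[perGeneDf$name]
    agg <- tapply(perGeneDf$n_exons, sf, mean)
    out$subfamily_mean_exons <- data.frame(
      subfamily = names(agg),
      mean_exons = as.numeric(agg),
      mean_exons_rounded = as.integer(round(as.numeric(agg))),
      row.names = NULL)
  }
  out
}
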