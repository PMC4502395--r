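#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges GRangesList start end width strand seqnames
#' @importFrom Biostrings AAStringSet DNAStringSet BStringSet
NULL

#' Gene models: ordered coding-exon coordinates per gene
#'
#' `GeneModels` wraps a [GenomicRanges::GRangesList] holding, for each gene,
#' its CDS segments in transcription order (ascending genomic start on the
#' `+` strand, descending on `-`).  Coordinates are 1-based closed, the
#' GRanges convention; all interval arithmetic goes through `width()` so the
#' external GFF3 dialect needs no conversion.
#'
#' @slot cds a `GRangesList`, one element per gene, named by gene id.
#' @export
setClass("GeneModels", representation(cds = "GRangesList"))

setValidity("GeneModels", function(object) {
  grl <- object@cds
  if (is.null(names(grl)) || anyDuplicated(names(grl)))
    return("gene ids must be unique and non-NULL")
  msgs <- character(0)
  for (i in seq_along(grl)) {
    gr <- grl[[i]]
    id <- names(grl)[i]
    if (length(gr) == 0L) {
      msgs <- c(msgs, sprintf("gene '%s' has no CDS segments", id)); next
    }
    if (length(unique(as.character(seqnames(gr)))) != 1L)
      msgs <- c(msgs, sprintf("gene '%s' spans multiple contigs", id))
    st <- unique(as.character(strand(gr)))
    if (length(st) != 1L || !st %in% c("+", "-"))
      msgs <- c(msgs, sprintf("gene '%s' must have a single strand in {+,-}", id))
    o <- order(start(gr))
    s <- start(gr)[o]; e <- end(gr)[o]
    if (length(gr) > 1L && any(s[-1L] <= e[-length(e)]))
      msgs <- c(msgs, sprintf("gene '%s' has overlapping CDS segments", id))
    # transcription order: ascending starts on +, descending on -
    if (st[1L] == "+" && is.unsorted(start(gr), strictly = TRUE) && length(gr) > 1L)
      msgs <- c(msgs, sprintf("gene '%s' (+) segments not in transcription order", id))
    if (st[1L] == "-" && length(gr) > 1L && is.unsorted(rev(start(gr)), strictly = TRUE))
      msgs <- c(msgs, sprintf("gene '%s' (-) segments not in transcription order", id))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneModels object
#'
#' @param cds a named `GRangesList` (or named list of `GRanges`) of CDS
#'   segments per gene, any order; segments are sorted into transcription
#'   order on construction.
#' @return a validated [GeneModels-class] object.
#' @export
GeneModels <- function(cds) {
  if (is.list(cds)) cds <- GRangesList(cds)
  sorted <- lapply(seq_along(cds), function(i) {
    gr <- cds[[i]]
    st <- as.character(strand(gr))[1L]
    gr[order(start(gr), decreasing = identical(st, "-"))]
  })
  names(sorted) <- names(cds)
  new("GeneModels", cds = GRangesList(sorted))
}

setMethod("show", "GeneModels", function(object) {
  n <- length(object@cds)
  cat(sprintf("GeneModels with %d gene%s on %d contig%s\n", n,
              if (n == 1) "" else "s",
              length(unique(geneContig(object))),
              if (length(unique(geneContig(object))) == 1) "" else "s"))
  ec <- exonCounts(object)
  if (n > 0)
    cat(sprintf("  exon counts: %d-%d; total CDS %d bp\n",
                min(ec), max(ec), sum(cdsLengths(object))))
})

#' @describeIn GeneModels-class number of genes
#' @param x,object a `GeneModels` object.
#' @export
setMethod("length", "GeneModels", function(x) length(x@cds))

#' Accessors for GeneModels
#'
#' `geneIds` returns gene identifiers; `cdsBy` the underlying `GRangesList`
#' (transcription order); `exonCounts` the number of CDS segments per gene;
#' `cdsLengths` the summed CDS length (cDNA length, bp) per gene;
#' `geneContig` and `geneStrand` the contig and strand per gene;
#' `geneSpan` the genomic extent (gene length, bp) per gene;
#' `cdsStart` the genomic coordinate of the first coding base in
#' transcription order (translation start).
#'
#' @param x a [GeneModels-class] object.
#' @return vectors named by gene id (or a `GRangesList` for `cdsBy`).
#' @name GeneModels-accessors
NULL

#' @rdname GeneModels-accessors
#' @export
geneIds <- function(x) names(x@cds)

#' @rdname GeneModels-accessors
#' @export
cdsBy <- function(x) x@cds

#' @rdname GeneModels-accessors
#' @export
exonCounts <- function(x) {
  stats::setNames(S4Vectors::elementNROWS(x@cds), names(x@cds))
}

#' @rdname GeneModels-accessors
#' @export
cdsLengths <- function(x) {
  stats::setNames(vapply(x@cds, function(gr) sum(width(gr)), integer(1)),
                  names(x@cds))
}

#' @rdname GeneModels-accessors
#' @export
geneContig <- function(x) {
  stats::setNames(vapply(x@cds, function(gr) as.character(seqnames(gr))[1L],
                         character(1)), names(x@cds))
}

#' @rdname GeneModels-accessors
#' @export
geneStrand <- function(x) {
  stats::setNames(vapply(x@cds, function(gr) as.character(strand(gr))[1L],
                         character(1)), names(x@cds))
}

#' @rdname GeneModels-accessors
#' @export
geneSpan <- function(x) {
  stats::setNames(vapply(x@cds, function(gr) {
    max(end(gr)) - min(start(gr)) + 1L
  }, integer(1)), names(x@cds))
}

#' @rdname GeneModels-accessors
#' @export
cdsStart <- function(x) {
  stats::setNames(vapply(x@cds, function(gr) {
    if (as.character(strand(gr))[1L] == "+") min(start(gr)) else max(end(gr))
  }, integer(1)), names(x@cds))
}

#' Exon lengths in transcription order
#' @param x a [GeneModels-class] object.
#' @return a named list of integer vectors (bp per CDS segment, 5' to 3').
#' @export
exonLengths <- function(x) {
  stats::setNames(lapply(x@cds, width), names(x@cds))
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Position-specific scoring matrix over the 20 amino acids
#'
#' Log2-odds scores (bits) per position against a background composition.
#'
#' @slot scores numeric matrix, positions x 20, columns named by residue.
#' @slot background numeric(20), background frequencies summing to 1.
#' @export
setClass("PSSM", representation(scores = "matrix", background = "numeric"))

setValidity("PSSM", function(object) {
  m <- object@scores
  if (!is.numeric(m) || is.null(colnames(m)) || !identical(colnames(m), AA20))
    return("scores must be a numeric matrix with the 20 standard residues as columns")
  if (nrow(m) < 1L) return("PSSM must have at least one position")
  b <- object@background
  if (length(b) != 20L || any(b <= 0) || abs(sum(b) - 1) > 1e-6)
    return("background must be 20 positive frequencies summing to 1")
  TRUE
})

setMethod("show", "PSSM", function(object) {
  cat(sprintf("PSSM: %d positions, consensus %s\n",
              nrow(object@scores), pssmConsensus(object)))
})

#' @describeIn PSSM-class number of positions (window width)
#' @param x a `PSSM` object.
#' @export
setMethod("length", "PSSM", function(x) nrow(x@scores))

#' Consensus sequence of a PSSM (highest-scoring residue per position)
#' @param pssm a [PSSM-class] object.
#' @return a character scalar of length `length(pssm)`.
#' @export
pssmConsensus <- function(pssm) {
  paste0(colnames(pssm@scores)[apply(pssm@scores, 1L, which.max)],
         collapse = "")
}

#' Simulation configuration for the synthetic dataset generator
#'
#' Holds every knob of [simulateGenome()] and [simulateCounts()].  Defaults
#' mirror the study design the pipeline was built around: 19 libraries
#' (4 organs x 2 replicates, 3 root tissues x 3 replicates, one library each
#' for control T0 and MeJA-treated T12 leaves), exon counts between 1 and
#' 12, negative-binomial counts, hard-zero means for organ-specific genes,
#' and planted 4-fold organ/tissue/MeJA effects.
#'
#' @slot seed integer; master seed, reproducible byte-for-byte.
#' @slot nContigs,nGenes genome layout.
#' @slot fractionBhlh fraction of genes receiving a planted bHLH domain.
#' @slot nVariants number of distinct planted domain variants (subfamily
#'   ground truth for the phylogeny stage).
#' @slot exonCountRange,intronLengthRange,proteinLengthRange integer ranges.
#' @slot intergenicRange intergenic spacer length range (bp); spacers are
#'   generated E-box free so promoter ground truth is exact.
#' @slot classCounts named integer vector: planted expression classes among
#'   bHLH genes (`flower_specific`, `leaf_specific`, `root_specific`,
#'   `stem_specific`, `root_enriched`, `periderm_enriched`, `meja_up`,
#'   `regulator`); remaining genes get class `none`.
#' @slot organFold,mejaFold planted fold sizes (> 1).
#' @slot depthRange library total-mapped-reads range.
#' @slot dispersion negative-binomial dispersion (variance = mu + phi*mu^2);
#'   0 gives Poisson draws.
#' @slot baselineMeanlog,baselineSdlog log-normal baseline expression (RPKM
#'   scale) parameters.
#' @slot promoterEboxFraction fraction of genes with planted promoter
#'   E-boxes.
#' @export
setClass("SimulationConfig", representation(
  seed = "integer",
  nContigs = "integer",
  nGenes = "integer",
  fractionBhlh = "numeric",
  nVariants = "integer",
  exonCountRange = "integer",
  intronLengthRange = "integer",
  proteinLengthRange = "integer",
  intergenicRange = "integer",
  classCounts = "integer",
  organFold = "numeric",
  mejaFold = "numeric",
  depthRange = "numeric",
  dispersion = "numeric",
  baselineMeanlog = "numeric",
  baselineSdlog = "numeric",
  promoterEboxFraction = "numeric"
))

PLANTED_CLASSES <- c("flower_specific", "leaf_specific", "root_specific",
                     "stem_specific", "root_enriched", "periderm_enriched",
                     "meja_up", "regulator")

setValidity("SimulationConfig", function(object) {
  msgs <- character(0)
  chkRange <- function(r, nm, lo = 1L) {
    if (length(r) != 2L || r[1L] > r[2L] || r[1L] < lo)
      sprintf("%s must be an increasing pair >= %d", nm, lo) else character(0)
  }
  if (object@fractionBhlh < 0 || object@fractionBhlh > 1)
    msgs <- c(msgs, "fractionBhlh must lie in [0,1]")
  if (object@promoterEboxFraction < 0 || object@promoterEboxFraction > 1)
    msgs <- c(msgs, "promoterEboxFraction must lie in [0,1]")
  if (object@organFold <= 1) msgs <- c(msgs, "organFold must be > 1")
  if (object@mejaFold <= 1) msgs <- c(msgs, "mejaFold must be > 1")
  if (object@dispersion < 0) msgs <- c(msgs, "dispersion must be >= 0")
  msgs <- c(msgs,
            chkRange(object@exonCountRange, "exonCountRange"),
            chkRange(object@intronLengthRange, "intronLengthRange", 4L),
            chkRange(object@proteinLengthRange, "proteinLengthRange", 30L),
            chkRange(object@intergenicRange, "intergenicRange", 50L),
            chkRange(object@depthRange, "depthRange", 1L))
  if (!all(names(object@classCounts) %in% PLANTED_CLASSES))
    msgs <- c(msgs, sprintf("unknown planted class: %s",
                            paste(setdiff(names(object@classCounts),
                                          PLANTED_CLASSES), collapse = ", ")))
  nb <- floor(object@nGenes * object@fractionBhlh)
  if (sum(object@classCounts) > nb)
    msgs <- c(msgs, "classCounts exceed the number of planted bHLH genes")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: seed %d, %d genes on %d contigs, ",
                     "%.0f%% bHLH, dispersion %.3g\n"),
              object@seed, object@nGenes, object@nContigs,
              100 * object@fractionBhlh, object@dispersion))
  cc <- object@classCounts
  cat("  planted classes:",
      paste(sprintf("%s=%d", names(cc), cc), collapse = ", "), "\n")
})

#' Build a SimulationConfig
#'
#' @param seed integer master seed.
#' @param nContigs,nGenes genome layout (default 4 contigs, 60 genes).
#' @param fractionBhlh fraction of genes with a planted domain (default 0.5).
#' @param nVariants planted domain variants (default 3).
#' @param exonCountRange exon count range (default 1:12).
#' @param intronLengthRange intron lengths, bp (default 60-300).
#' @param proteinLengthRange protein lengths, aa (default 80-300).
#' @param intergenicRange intergenic spacer, bp (default 1100-1400; wide
#'   enough that promoter windows of neighbouring genes never share
#'   sequence).
#' @param classCounts planted expression class counts (see
#'   [SimulationConfig-class] for the defaults).
#' @param organFold,mejaFold planted fold sizes (default 4).
#' @param depthRange library depth range (default 8e6-1.2e7 mapped reads).
#' @param dispersion NB dispersion (default 0.05; 0 = Poisson).
#' @param baselineMeanlog,baselineSdlog baseline log-normal parameters
#'   (default log(50), 0.3 on the RPKM scale).
#' @param promoterEboxFraction fraction of genes with planted promoter
#'   E-boxes (default 0.6).
#' @return a validated [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(seed = 7, nGenes = 20)
#' cfg
#' @export
simulationConfig <- function(seed = 1L,
                             nContigs = 4L,
                             nGenes = 60L,
                             fractionBhlh = 0.5,
                             nVariants = 3L,
                             exonCountRange = c(1L, 12L),
                             intronLengthRange = c(60L, 300L),
                             proteinLengthRange = c(80L, 300L),
                             intergenicRange = c(1100L, 1400L),
                             classCounts = c(flower_specific = 3L,
                                             leaf_specific = 2L,
                                             root_specific = 3L,
                                             stem_specific = 2L,
                                             root_enriched = 4L,
                                             periderm_enriched = 3L,
                                             meja_up = 4L,
                                             regulator = 3L),
                             organFold = 4,
                             mejaFold = 4,
                             depthRange = c(8e6, 1.2e7),
                             dispersion = 0.05,
                             baselineMeanlog = log(50),
                             baselineSdlog = 0.3,
                             promoterEboxFraction = 0.6) {
  classCounts <- stats::setNames(as.integer(classCounts), names(classCounts))
  # shrink the default class layout round-robin for small genomes
  nb <- floor(as.integer(nGenes) * fractionBhlh)
  while (sum(classCounts) > nb && any(classCounts > 0L)) {
    i <- which.max(classCounts)
    classCounts[i] <- classCounts[i] - 1L
  }
  new("SimulationConfig",
      seed = as.integer(seed), nContigs = as.integer(nContigs),
      nGenes = as.integer(nGenes), fractionBhlh = fractionBhlh,
      nVariants = as.integer(nVariants),
      exonCountRange = as.integer(exonCountRange),
      intronLengthRange = as.integer(intronLengthRange),
      proteinLengthRange = as.integer(proteinLengthRange),
      intergenicRange = as.integer(intergenicRange),
      classCounts = classCounts,
      organFold = organFold, mejaFold = mejaFold,
      depthRange = as.numeric(depthRange), dispersion = dispersion,
      baselineMeanlog = baselineMeanlog, baselineSdlog = baselineSdlog,
      promoterEboxFraction = promoterEboxFraction)
}
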