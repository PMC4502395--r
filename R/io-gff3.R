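#' Read gene models from a GFF3 file
#'
#' Expects `gene`, `mRNA` and `CDS` features with `ID`/`Parent` attributes;
#' each CDS is resolved to its gene through the Parent chain (CDS -> mRNA ->
#' gene, or CDS -> gene directly).  CDS segments of one gene must not
#' overlap.  Segments are returned in transcription order (see
#' [GeneModels-class]).
#'
#' @param path GFF3 file path.
#' @return a [GeneModels-class] object.
#' @export
readGff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gff <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gff$type)
  ids <- as.character(gff$ID)
  # map feature id -> parent id (first parent; single-isoform models assumed)
  parent <- vapply(gff$Parent, function(p)
    if (length(p)) as.character(p)[1L] else NA_character_, character(1))
  id2parent <- stats::setNames(parent, ids)
  geneIdsAll <- ids[type == "gene"]
  resolveGene <- function(p) {
    seen <- character(0)
    while (!is.na(p) && !(p %in% geneIdsAll)) {
      if (p %in% seen) return(NA_character_)
      seen <- c(seen, p)
      p <- if (p %in% names(id2parent)) id2parent[[p]] else NA_character_
    }
    p
  }
  cdsIdx <- which(type == "CDS")
  if (length(cdsIdx) == 0L) stop("GFF3 format error: no CDS features in ", path)
  cdsGene <- vapply(parent[cdsIdx], resolveGene, character(1))
  if (anyNA(cdsGene)) {
    bad <- which(is.na(cdsGene))[1L]
    stop("GFF3 format error: CDS without resolvable gene parent (line feature ",
         cdsIdx[bad], ", Parent='", parent[cdsIdx][bad], "')")
  }
  cds <- gff[cdsIdx]
  byGene <- split(GenomicRanges::granges(cds), cdsGene)
  for (g in names(byGene)) {
    gr <- byGene[[g]]
    o <- order(GenomicRanges::start(gr))
    s <- GenomicRanges::start(gr)[o]; e <- GenomicRanges::end(gr)[o]
    if (length(gr) > 1L && any(s[-1L] <= e[-length(e)]))
      stop("GFF3 format error: overlapping CDS segments in gene '", g, "'")
  }
  GeneModels(as.list(byGene))
}

#' Write gene models as GFF3
#'
#' Emits one `gene`, one `mRNA` and the CDS rows per gene, with `ID`/`Parent`
#' attributes, suitable for [readGff3()] round-trips.
#'
#' @param models a [GeneModels-class] object.
#' @param path output path.
#' @param source value for the GFF3 source column (default
#'   `"bhlhProspector"`).
#' @return `path`, invisibly.
#' @export
writeGff3 <- function(models, path, source = "bhlhProspector") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  grl <- cdsBy(models)
  for (g in names(grl)) {
    gr <- grl[[g]]
    contig <- as.character(seqnames(gr))[1L]
    st <- as.character(strand(gr))[1L]
    lo <- min(start(gr)); hi <- max(end(gr))
    writeLines(sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       contig, source, lo, hi, st, g), con)
    writeLines(sprintf("%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                       contig, source, lo, hi, st, g, g), con)
    # CDS rows written in genomic order; phase follows transcription order
    lens <- width(gr)
    phases <- integer(length(lens))
    cum <- 0L
    for (i in seq_along(lens)) {
      phases[i] <- (3L - cum %% 3L) %% 3L
      cum <- cum + lens[i]
    }
    ord <- order(start(gr))
    for (i in ord) {
      writeLines(sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s.t1",
                         contig, source, start(gr)[i], end(gr)[i], st,
                         phases[i], g, g), con)
    }
  }
  invisible(path)
}
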