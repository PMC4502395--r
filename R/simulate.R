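# Swiss-Prot-like background amino-acid composition for non-domain protein
# sequence; the PSSM background stays uniform (see buildPssm()).
BG_AA_FREQ <- c(A = 0.0825, R = 0.0553, N = 0.0406, D = 0.0545, C = 0.0137,
                Q = 0.0393, E = 0.0675, G = 0.0707, H = 0.0227, I = 0.0596,
                L = 0.0966, K = 0.0584, M = 0.0242, F = 0.0386, P = 0.0470,
                S = 0.0656, T = 0.0534, W = 0.0108, Y = 0.0292, V = 0.0687)

SIM_CONDITIONS <- data.frame(
  condition = rep(c("flower", "leaf", "root", "stem",
                    "periderm", "phloem", "xylem", "T0", "T12"),
                  times = c(2, 2, 2, 2, 3, 3, 3, 1, 1)),
  stringsAsFactors = FALSE)
SIM_CONDITIONS$replicate <- unlist(lapply(
  rle(SIM_CONDITIONS$condition)$lengths, seq_len))
SIM_CONDITIONS$library_id <- paste0(SIM_CONDITIONS$condition, "_",
                                    SIM_CONDITIONS$replicate)

#' Path of the packaged synthetic bHLH seed alignment
#'
#' A small gap-free alignment of synthetic bHLH-like domain sequences
#' (basic region followed by two helices around a loop), constructed for
#' this package; it stands in for a curated domain seed alignment and is
#' *not* derived from any database entry.
#'
#' @return file path inside the installed package.
#' @export
bhlhSeedAlignmentPath <- function() {
  system.file("extdata", "bhlh_seed_synthetic.fasta",
              package = "bhlhProspector", mustWork = TRUE)
}

sampleAa <- function(n, freq = BG_AA_FREQ) {
  paste(sample(names(freq), n, replace = TRUE, prob = freq), collapse = "")
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random DNA free of E-boxes (CANNTG); also used to scrub assembled spacers
scrubEbox <- function(seq) {
  s <- Biostrings::DNAString(seq)
  repeat {
    hits <- Biostrings::matchPattern("CANNTG", s, fixed = FALSE)
    if (length(hits) == 0L) break
    for (p in Biostrings::start(hits))
      s <- Biostrings::replaceLetterAt(s, p, "G")  # kill the leading C
  }
  as.character(s)
}

randomDnaNoEbox <- function(n) scrubEbox(randomDna(n))

# codons per amino acid (standard code, stops excluded)
codonTable <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)[AA20]
}

reverseTranslate <- function(protein, codons = codonTable()) {
  chars <- strsplit(protein, "")[[1L]]
  paste(vapply(chars, function(a) {
    opts <- codons[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

# planted domain variants: the PSSM consensus with variant-specific
# substitutions at a fixed position subset, so variants form separable
# clusters while still scoring far above background
domainVariants <- function(pssm, nVariants) {
  cons <- strsplit(pssmConsensus(pssm), "")[[1L]]
  L <- length(cons)
  varPos <- sample(seq_len(L), max(3L, round(0.3 * L)))
  lapply(seq_len(nVariants), function(v) {
    out <- cons
    out[varPos] <- sample(AA20, length(varPos), replace = TRUE)
    out
  })
}

sampleDomain <- function(variant, profile, mutProb = 0.05) {
  out <- variant
  flip <- which(stats::runif(length(out)) < mutProb)
  for (p in flip)
    out[p] <- sample(AA20, 1L, prob = profile[p, ])
  paste(out, collapse = "")
}

#' Simulate a toy genome with planted bHLH genes, promoters and truth labels
#'
#' Generates contigs carrying protein-coding genes separated by E-box-free
#' intergenic spacers.  A configured fraction of genes receives a planted
#' bHLH-like domain (one of `nVariants` separable variants sampled around
#' the seed-PSSM consensus); every CDS starts with ATG, ends with a single
#' stop, has length divisible by 3 and no internal stop, and is split into
#' 1-12 exons with random introns.  Promoters of a configured fraction of
#' genes carry planted E-boxes at recorded upstream offsets; all other
#' intergenic sequence is E-box free, so promoter-scan ground truth is
#' exact.  Byte-identical outputs for identical config + seed.
#'
#' @param config a [SimulationConfig-class].
#' @param pssm optional [PSSM-class] used both to plant domains and,
#'   downstream, to detect them; default builds one from
#'   [bhlhSeedAlignmentPath()].
#' @return list with `genome` (`DNAStringSet`), `models`
#'   ([GeneModels-class]), `proteome` (`AAStringSet`), `truth`
#'   (data.frame: gene/contig/strand, `is_bhlh`, `variant`, `class`,
#'   `baseline_rpkm`, `ebox_planted`, `ebox_offsets`, `n_exons`,
#'   `cdna_length`, `protein_length`) and `pssm`.
#' @export
simulateGenome <- function(config, pssm = NULL) {
  methods::validObject(config)
  set.seed(config@seed)
  if (is.null(pssm))
    pssm <- buildPssm(readFasta(bhlhSeedAlignmentPath(), "AA"))
  profile <- pssmProfile(pssm)
  domLen <- nrow(profile)
  nG <- config@nGenes
  ids <- sprintf("g%03d", seq_len(nG))
  isBhlh <- rep(FALSE, nG)
  isBhlh[sample(nG, floor(nG * config@fractionBhlh))] <- TRUE
  variants <- domainVariants(pssm, config@nVariants)
  variantOf <- rep(NA_integer_, nG)
  variantOf[isBhlh] <- sample(rep_len(seq_len(config@nVariants),
                                      sum(isBhlh)))
  # expression classes among planted genes
  class_ <- rep("none", nG)
  bhlhIdx <- sample(which(isBhlh))
  cc <- config@classCounts
  pos <- 1L
  for (cl in names(cc)) {
    if (cc[[cl]] == 0L) next
    class_[bhlhIdx[pos:(pos + cc[[cl]] - 1L)]] <- cl
    pos <- pos + cc[[cl]]
  }
  baseline <- stats::rlnorm(nG, config@baselineMeanlog, config@baselineSdlog)
  eboxFlag <- rep(FALSE, nG)
  eboxFlag[sample(nG, round(nG * config@promoterEboxFraction))] <- TRUE
  codons <- codonTable()
  contigOf <- rep_len(seq_len(config@nContigs), nG)

  perGene <- vector("list", nG)
  for (g in seq_len(nG)) {
    pl <- sample(config@proteinLengthRange[1L]:config@proteinLengthRange[2L], 1L)
    body <- sampleAa(pl - 1L)
    if (isBhlh[g]) {
      dom <- sampleDomain(variants[[variantOf[g]]], profile)
      at <- sample.int(nchar(body) - domLen + 1L, 1L)
      body <- paste0(substr(body, 1L, at - 1L), dom,
                     substr(body, at + domLen, nchar(body)))
    }
    protein <- paste0("M", body)
    cds <- paste0(reverseTranslate(protein, codons),
                  sample(c("TAA", "TAG", "TGA"), 1L))
    Lc <- nchar(cds)
    kMax <- min(config@exonCountRange[2L], Lc %/% 3L)
    k <- sample(config@exonCountRange[1L]:kMax, 1L)
    cuts <- if (k > 1L) sort(sample(seq_len(Lc - 1L), k - 1L)) else integer(0)
    exLens <- diff(c(0L, cuts, Lc))
    intLens <- if (k > 1L)
      sample(config@intronLengthRange[1L]:config@intronLengthRange[2L],
             k - 1L, replace = TRUE) else integer(0)
    introns <- vapply(intLens, function(n)
      paste0("GT", randomDna(n - 4L), "AG"), character(1))
    exStarts <- integer(k); exEnds <- integer(k)  # within gene body, tx strand
    bodySeq <- character(0)
    cursor <- 0L
    cdsPos <- 0L
    for (e in seq_len(k)) {
      exSeq <- substr(cds, cdsPos + 1L, cdsPos + exLens[e])
      cdsPos <- cdsPos + exLens[e]
      exStarts[e] <- cursor + 1L
      exEnds[e] <- cursor + exLens[e]
      bodySeq <- c(bodySeq, exSeq)
      cursor <- cursor + exLens[e]
      if (e < k) {
        bodySeq <- c(bodySeq, introns[e])
        cursor <- cursor + intLens[e]
      }
    }
    perGene[[g]] <- list(protein = protein, cds = cds,
                         body = paste(bodySeq, collapse = ""),
                         exStarts = exStarts, exEnds = exEnds,
                         exLens = exLens,
                         strand = sample(c("+", "-"), 1L))
  }

  contigSeqs <- character(config@nContigs)
  names(contigSeqs) <- sprintf("ctg%02d", seq_len(config@nContigs))
  grList <- list()
  eboxCount <- integer(nG)
  eboxOffsets <- character(nG)
  for (ct in seq_len(config@nContigs)) {
    genesHere <- which(contigOf == ct)
    seqParts <- character(0)
    offset <- 0L
    geneStartAt <- integer(length(genesHere))
    for (gi in seq_along(genesHere)) {
      g <- genesHere[gi]
      spacer <- randomDnaNoEbox(
        sample(config@intergenicRange[1L]:config@intergenicRange[2L], 1L))
      seqParts <- c(seqParts, spacer)
      offset <- offset + nchar(spacer)
      info <- perGene[[g]]
      B <- nchar(info$body)
      genomicBody <- if (info$strand == "+") info$body else
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(info$body)))
      seqParts <- c(seqParts, genomicBody)
      geneStartAt[gi] <- offset + 1L
      # exon genomic coordinates
      if (info$strand == "+") {
        s <- offset + info$exStarts; e <- offset + info$exEnds
      } else {
        s <- offset + (B - info$exEnds) + 1L
        e <- offset + (B - info$exStarts) + 1L
      }
      grList[[ids[g]]] <- GenomicRanges::GRanges(
        names(contigSeqs)[ct],
        IRanges::IRanges(start = s, end = e),
        strand = info$strand)
      offset <- offset + B
    }
    tail_ <- randomDnaNoEbox(
      sample(config@intergenicRange[1L]:config@intergenicRange[2L], 1L))
    seqParts <- c(seqParts, tail_)
    contig <- paste(seqParts, collapse = "")
    # plant promoter E-boxes now that coordinates are final
    contigChars <- Biostrings::DNAString(contig)
    for (gi in seq_along(genesHere)) {
      g <- genesHere[gi]
      if (!eboxFlag[g]) next
      info <- perGene[[g]]
      gr <- grList[[ids[g]]]
      nBox <- sample(1:3, 1L)
      offs <- sort(sample(seq(10L, 480L, by = 12L), nBox))  # upstream dist
      hexes <- vapply(seq_len(nBox), function(i)
        paste0("CA", randomDna(2L), "TG"), character(1))
      for (b in seq_len(nBox)) {
        if (info$strand == "+") {
          sPos <- min(GenomicRanges::start(gr)) - offs[b] - 6L
          hex <- hexes[b]
        } else {
          sPos <- max(GenomicRanges::end(gr)) + offs[b] + 1L
          hex <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(hexes[b])))
        }
        contigChars <- Biostrings::replaceLetterAt(
          contigChars, sPos:(sPos + 5L), strsplit(hex, "")[[1L]])
      }
      eboxCount[g] <- nBox
      eboxOffsets[g] <- paste(offs, collapse = ",")
    }
    contigSeqs[ct] <- as.character(contigChars)
  }
  # repair accidental E-boxes created at planting junctions, outside the
  # planted hexamers themselves
  for (ct in names(contigSeqs)) {
    genesHere <- which(contigOf == match(ct, names(contigSeqs)))
    s <- Biostrings::DNAString(contigSeqs[[ct]])
    planted <- integer(0)
    for (g in genesHere) {
      if (!eboxFlag[g] || eboxCount[g] == 0L) next
      gr <- grList[[ids[g]]]
      offs <- as.integer(strsplit(eboxOffsets[g], ",")[[1L]])
      starts <- if (perGene[[g]]$strand == "+")
        min(GenomicRanges::start(gr)) - offs - 6L
      else max(GenomicRanges::end(gr)) + offs + 1L
      planted <- c(planted, unlist(lapply(starts, function(p) p:(p + 5L))))
    }
    guard <- 0L
    repeat {
      hitStarts <- Biostrings::start(
        Biostrings::matchPattern("CANNTG", s, fixed = FALSE))
      # only hits that touch a planted hexamer can be junction artefacts
      # (spacers are pre-scrubbed; gene-body hits are legitimate and are
      # never part of a promoter window); a hit is fine iff fully planted
      bad <- hitStarts[vapply(hitStarts, function(p) {
        span <- p:(p + 5L)
        any(span %in% planted) && !all(span %in% planted)
      }, logical(1))]
      if (!length(bad) || guard > 50L) break
      guard <- guard + 1L
      for (p in bad) {
        mutPos <- setdiff(p:(p + 5L), planted)[1L]
        s <- Biostrings::replaceLetterAt(s, mutPos, "G")
      }
    }
    contigSeqs[[ct]] <- as.character(s)
  }

  models <- GeneModels(grList[ids])
  proteome <- Biostrings::AAStringSet(
    stats::setNames(vapply(perGene, `[[`, character(1), "protein"), ids))
  truth <- data.frame(
    gene_id = ids,
    contig = names(contigSeqs)[contigOf],
    strand = vapply(perGene, `[[`, character(1), "strand"),
    is_bhlh = isBhlh,
    variant = variantOf,
    class = class_,
    baseline_rpkm = baseline,
    ebox_planted = eboxCount,
    ebox_offsets = eboxOffsets,
    n_exons = vapply(perGene, function(x) length(x$exLens), integer(1)),
    cdna_length = vapply(perGene, function(x) nchar(x$cds), integer(1)),
    protein_length = vapply(perGene, function(x) nchar(x$protein),
                            integer(1)))
  list(genome = Biostrings::DNAStringSet(contigSeqs), models = models,
       proteome = proteome, truth = truth, pssm = pssm)
}

classMultiplier <- function(class_, condition, organFold, mejaFold) {
  F <- organFold
  tissue <- condition %in% c("periderm", "phloem", "xylem")
  switch(class_,
    none = 1,
    flower_specific = if (condition == "flower") 1 else 0,
    leaf_specific = if (condition %in% c("leaf", "T0", "T12")) 1 else 0,
    root_specific = if (condition == "root" || tissue) 1 else 0,
    stem_specific = if (condition == "stem") 1 else 0,
    root_enriched = if (condition == "root" || tissue) F else 1,
    periderm_enriched = if (condition == "periderm") F else 1,
    meja_up = if (condition == "T12") mejaFold else 1,
    regulator = if (condition == "root" || tissue) F
      else if (condition == "T12") mejaFold else 1,
    stop("unknown class ", class_))
}

#' Simulate a 19-library count table from planted truth
#'
#' Library layout mirrors the study design: 2 replicates for each of 4
#' organs, 3 for each of 3 root tissues, and one library each for T0
#' (carrier control) and T12 (MeJA-treated) leaves.  Counts are negative
#' binomial with mean `depth x (cDNA length / 1e3) x (baseline / 1e3) x
#' class multiplier` — i.e. the planted baseline is on the RPKM scale —
#' and variance `mu + dispersion * mu^2`; dispersion 0 gives Poisson
#' draws.  Organ-/tissue-specific classes have hard-zero means outside
#' their home condition.
#'
#' @param truth truth table from [simulateGenome()].
#' @param models the matching [GeneModels-class].
#' @param config the [SimulationConfig-class] used for the genome.
#' @param seed RNG seed for the count draws (default `config@seed + 1`).
#' @return a `SummarizedExperiment` with assay `counts` and library
#'   metadata (`library_id`, `condition`, `replicate`, `total_mapped`) as
#'   `colData`.
#' @export
simulateCounts <- function(truth, models, config,
                           seed = config@seed + 1L) {
  set.seed(seed)
  libs <- SIM_CONDITIONS
  libs$total_mapped <- round(stats::runif(nrow(libs), config@depthRange[1L],
                                          config@depthRange[2L]))
  L <- cdsLengths(models)[truth$gene_id]
  m <- matrix(0L, nrow(truth), nrow(libs),
              dimnames = list(truth$gene_id, libs$library_id))
  for (j in seq_len(nrow(libs))) {
    mult <- vapply(truth$class, classMultiplier, numeric(1),
                   condition = libs$condition[j],
                   organFold = config@organFold,
                   mejaFold = config@mejaFold)
    mu <- truth$baseline_rpkm * mult * (L / 1e3) *
      (libs$total_mapped[j] / 1e6)
    cnt <- if (config@dispersion > 1e-8)
      stats::rnbinom(length(mu), mu = mu, size = 1 / config@dispersion)
    else stats::rpois(length(mu), mu)
    cnt[mu == 0] <- 0L
    m[, j] <- cnt
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(libs, row.names = libs$library_id))
}

#' Expected expression-filter truth implied by the planted classes
#'
#' Applies the filter definitions to the *noiseless* planted means, giving
#' the sets a perfect (zero-noise) analysis would recover; used to score
#' recovery on simulated data.  Note the root-enrichment set includes
#' root-specific genes (zero elsewhere trivially satisfies any fold) and
#' the `regulator` class satisfies both root enrichment and MeJA
#' up-regulation.
#'
#' @param truth truth table from [simulateGenome()].
#' @param minRpkm the filters' minimum-RPKM threshold (default 1).
#' @return list of character gene-id vectors: `root_specific`,
#'   `flower_specific`, `leaf_specific`, `stem_specific`, `root_enriched`,
#'   `periderm_enriched`, `meja_up`, `organ_detected`.
#' @export
truthExpectedFlags <- function(truth, minRpkm = 1) {
  cls <- truth$class
  ok <- truth$baseline_rpkm > minRpkm
  list(
    flower_specific = truth$gene_id[cls == "flower_specific"],
    leaf_specific = truth$gene_id[cls == "leaf_specific"],
    root_specific = truth$gene_id[cls == "root_specific"],
    stem_specific = truth$gene_id[cls == "stem_specific"],
    root_enriched = truth$gene_id[
      (cls %in% c("root_enriched", "regulator")) |
        (cls == "root_specific" & ok)],
    periderm_enriched = truth$gene_id[cls == "periderm_enriched" & ok],
    meja_up = truth$gene_id[cls %in% c("meja_up", "regulator")],
    # every planted class has a nonzero mean in at least one organ
    organ_detected = truth$gene_id)
}
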