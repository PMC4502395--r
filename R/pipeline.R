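#' Default pipeline configuration
#'
#' The full configuration schema with every tunable of every stage.  User
#' configs (R lists or YAML files) are merged over these defaults;
#' unknown keys are rejected by name.
#'
#' @return nested named list.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    outdir = "bhlh_out",
    run_id = "run1",
    inputs = list(genome = NULL, gff = NULL, proteome = NULL,
                  counts = NULL, counts_meta = NULL,
                  seed_alignment = NULL, elements = NULL),
    simulate = list(enabled = TRUE, n_genes = 60L, n_contigs = 4L,
                    fraction_bhlh = 0.5, dispersion = 0.05,
                    organ_fold = 4, meja_fold = 4,
                    promoter_ebox_fraction = 0.6),
    identify = list(threshold_bits = NULL, prefix = "bHLH"),
    structure = list(policy = "terminal_virtual_zero"),
    tree = list(replicates = 200L, min_support = 50,
                max_depth_fraction = 0.5, deletion = "pairwise"),
    motifs = list(pwms = NULL, threshold_bits = NULL),
    express = list(distance = "correlation", linkage = "average"),
    filters = list(fold = 2, min_rpkm = 1, meja_fold = 2,
                   meja_min_rpkm = 1, meja_pseudocount = 0.1),
    prioritize = list(rule = DEFAULT_RULE,
                      regulator_subfamilies = character(0)),
    promoters = list(length = 500L, both_strands = TRUE))
}

mergeConfig <- function(user, defaults, path = character(0)) {
  if (is.null(user)) return(defaults)
  if (!is.list(user))
    stop("config validation error: '", paste(path, collapse = "."),
         "' must be a section")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("config validation error: unknown key '",
         paste(c(path, unknown[1L]), collapse = "."), "'")
  out <- defaults
  for (k in names(user)) {
    out[[k]] <- if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      mergeConfig(user[[k]], defaults[[k]], c(path, k))
    else user[[k]]
  }
  out
}

#' Validate and complete a pipeline configuration
#'
#' @param config partial configuration (nested list) or a YAML file path.
#' @return the completed configuration.
#' @export
pipelineConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  mergeConfig(config, defaultPipelineConfig())
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full characterisation pipeline
#'
#' Stages run in dependency order: simulate (optional) -> identify ->
#' props -> tree -> structure -> motifs -> express -> filters ->
#' prioritize -> promoters.  Every stage writes its outputs under
#' `outdir`, first with a `.partial` suffix, renamed on stage completion
#' so an aborted run is recognisable.  The returned manifest records, per
#' stage, the output paths, their md5 checksums and the parameters used
#' (defaults included), and is written to `outdir/manifest.yaml`.
#' Identical config + seed give identical checksums.
#'
#' @param config a configuration from [pipelineConfig()] (partial lists
#'   and YAML paths accepted).
#' @return the manifest (nested list), invisibly.
#' @export
runAll <- function(config = list()) {
  cfg <- pipelineConfig(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(run_id = cfg$run_id, seed = cfg$seed, stages = list())
  out <- function(f) file.path(cfg$outdir, f)

  finishStage <- function(stage, files, params) {
    for (f in files) {
      if (file.exists(paste0(f, ".partial")))
        file.rename(paste0(f, ".partial"), f)
    }
    manifest$stages[[stage]] <<- list(
      outputs = as.list(files),
      md5 = as.list(unname(tools::md5sum(files))),
      parameters = params)
  }
  runStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- simulate -------------------------------------------------------
  if (isTRUE(cfg$simulate$enabled)) {
    runStage("simulate", {
      simCfg <- simulationConfig(
        seed = cfg$seed,
        nGenes = cfg$simulate$n_genes,
        nContigs = cfg$simulate$n_contigs,
        fractionBhlh = cfg$simulate$fraction_bhlh,
        dispersion = cfg$simulate$dispersion,
        organFold = cfg$simulate$organ_fold,
        mejaFold = cfg$simulate$meja_fold,
        promoterEboxFraction = cfg$simulate$promoter_ebox_fraction)
      sim <- simulateGenome(simCfg)
      counts <- simulateCounts(sim$truth, sim$models, simCfg)
      files <- c(genome = out("genome.fasta"), gff = out("annotation.gff3"),
                 proteome = out("proteome.fasta"), counts = out("counts.tsv"),
                 meta = out("libraries.tsv"), truth = out("truth.tsv"))
      writeFasta(sim$genome, paste0(files["genome"], ".partial"))
      writeGff3(sim$models, paste0(files["gff"], ".partial"))
      writeFasta(sim$proteome, paste0(files["proteome"], ".partial"))
      writeCounts(counts, paste0(files["counts"], ".partial"),
                  paste0(files["meta"], ".partial"))
      writeTsv(sim$truth, paste0(files["truth"], ".partial"))
      finishStage("simulate", files,
                  cfg$simulate[setdiff(names(cfg$simulate), "enabled")])
      cfg$inputs$genome <- files[["genome"]]
      cfg$inputs$gff <- files[["gff"]]
      cfg$inputs$proteome <- files[["proteome"]]
      cfg$inputs$counts <- files[["counts"]]
      cfg$inputs$counts_meta <- files[["meta"]]
    })
  }
  for (need in c("genome", "gff", "proteome", "counts", "counts_meta")) {
    if (is.null(cfg$inputs[[need]]))
      stop("pipeline input error: inputs$", need,
           " required when simulate is disabled")
  }

  genome <- readFasta(cfg$inputs$genome, "DNA")
  models <- readGff3(cfg$inputs$gff)
  proteome <- readFasta(cfg$inputs$proteome, "AA")
  counts <- readCounts(cfg$inputs$counts, cfg$inputs$counts_meta)
  seedAln <- readFasta(
    if (is.null(cfg$inputs$seed_alignment)) bhlhSeedAlignmentPath()
    else cfg$inputs$seed_alignment, "AA")
  pssm <- buildPssm(seedAln)

  # --- identify -------------------------------------------------------
  members <- NULL
  runStage("identify", {
    members <- identifyFamily(proteome, models, pssm, genome = genome,
                               thresholdBits = cfg$identify$threshold_bits,
                               prefix = cfg$identify$prefix)
    f <- out("members.tsv")
    writeTsv(as.data.frame(members), paste0(f, ".partial"))
    finishStage("identify", c(members = f),
                list(threshold_bits =
                       S4Vectors::metadata(members)$threshold_bits,
                     prefix = cfg$identify$prefix))
  })
  if (nrow(members) == 0L)
    stop("pipeline stage 'identify' found no family members")

  # --- props ----------------------------------------------------------
  runStage("props", {
    props <- proteinProperties(proteome, members)
    f <- out("properties.tsv")
    writeTsv(props, paste0(f, ".partial"))
    finishStage("props", c(properties = f), list(pka_set = "emboss"))
  })

  # --- tree -----------------------------------------------------------
  subfam <- NULL
  runStage("tree", {
    doms <- substr(as.character(proteome[members$gene_id]),
                   members$domain_start, members$domain_end)
    names(doms) <- members$name
    aln <- progressiveAlign(doms)
    tr <- if (length(aln) >= 4L)
      bootstrapSupports(aln, replicates = cfg$tree$replicates,
                        seed = cfg$seed, deletion = cfg$tree$deletion)
    else njTree(pDistance(aln, cfg$tree$deletion))
    subfam <- assignSubfamilies(
      tr, minSupport = cfg$tree$min_support,
      maxDepthFraction = cfg$tree$max_depth_fraction)
    f1 <- out("tree.nwk"); f2 <- out("subfamilies.tsv")
    writeNewick(tr, paste0(f1, ".partial"))
    writeTsv(data.frame(name = names(subfam), subfamily = unname(subfam)),
             paste0(f2, ".partial"))
    finishStage("tree", c(tree = f1, subfamilies = f2),
                cfg$tree)
  })

  # --- structure ------------------------------------------------------
  runStage("structure", {
    ss <- summarizeStructures(members, models, subfamilies = subfam,
                              policy = cfg$structure$policy)
    f1 <- out("structure_per_gene.tsv"); f2 <- out("structure_summary.tsv")
    writeTsv(ss$per_gene, paste0(f1, ".partial"))
    summaryDf <- data.frame(
      metric = c("total_exons", "total_introns",
                 paste0("introns_phase", 0:2),
                 paste0("symmetric_phase", 0:2), "intronless_genes"),
      value = c(ss$total_exons, ss$total_introns, ss$phase_histogram,
                ss$symmetric_by_phase, length(ss$intronless)))
    writeTsv(summaryDf, paste0(f2, ".partial"))
    finishStage("structure", c(per_gene = f1, summary = f2),
                list(policy = cfg$structure$policy))
  })

  # --- motifs ---------------------------------------------------------
  runStage("motifs", {
    motifs <- if (is.null(cfg$motifs$pwms)) list(motif1 = pssm)
    else readMotifSet(cfg$motifs$pwms)
    thr <- cfg$motifs$threshold_bits
    if (is.null(thr))
      thr <- vapply(motifs, choosePssmThreshold, numeric(1))
    occ <- scanMotifs(proteome[members$gene_id], motifs, thr)
    occ$protein <- members$name[match(occ$protein, members$gene_id)]
    dist <- motifSubfamilyMatrix(occ, subfam)
    f1 <- out("motif_occurrences.tsv"); f2 <- out("motif_subfamily.tsv")
    writeTsv(occ, paste0(f1, ".partial"))
    writeTsv(data.frame(subfamily = rownames(dist$presence),
                        dist$presence, check.names = FALSE),
             paste0(f2, ".partial"))
    finishStage("motifs", c(occurrences = f1, subfamily = f2),
                list(threshold_bits = as.list(thr)))
  })

  # --- express --------------------------------------------------------
  condRpkm <- NULL; rpkm <- NULL
  runStage("express", {
    rpkm <- computeRpkm(counts, cdsLengths(models))
    condRpkm <- aggregateReplicates(rpkm)
    f1 <- out("rpkm.tsv"); f2 <- out("rpkm_condition.tsv")
    f3 <- out("cluster_order.tsv")
    m <- SummarizedExperiment::assay(rpkm, "rpkm")
    writeTsv(data.frame(gene_id = rownames(m), m, check.names = FALSE),
             paste0(f1, ".partial"))
    mc <- SummarizedExperiment::assay(condRpkm, "rpkm")
    writeTsv(data.frame(gene_id = rownames(mc), mc, check.names = FALSE),
             paste0(f2, ".partial"))
    organ <- c("flower", "leaf", "root", "stem")
    mcMembers <- mc[members$gene_id, organ, drop = FALSE]
    detected <- rownames(mcMembers)[rowSums(mcMembers > 0) > 0]
    cl <- if (length(detected) >= 2L)
      hierarchicalCluster(condRpkm[detected, organ],
                          distance = cfg$express$distance,
                          linkage = cfg$express$linkage)
    else list(order = detected)
    writeTsv(data.frame(order = seq_along(cl$order), gene_id = cl$order),
             paste0(f3, ".partial"))
    finishStage("express", c(rpkm = f1, condition = f2, cluster = f3),
                cfg$express)
  })

  # --- filters --------------------------------------------------------
  flt <- NULL
  runStage("filters", {
    memberRpkm <- condRpkm[members$gene_id, ]
    spec <- detectionAndSpecificity(memberRpkm)
    rootEnr <- enrichmentFilter(memberRpkm, "root",
                                c("flower", "leaf", "stem"),
                                fold = cfg$filters$fold,
                                minRpkm = cfg$filters$min_rpkm)
    periEnr <- enrichmentFilter(memberRpkm, "periderm",
                                c("phloem", "xylem"),
                                fold = cfg$filters$fold,
                                minRpkm = cfg$filters$min_rpkm)
    meja <- mejaResponse(memberRpkm, fold = cfg$filters$meja_fold,
                         minRpkm = cfg$filters$meja_min_rpkm,
                         pseudocount = cfg$filters$meja_pseudocount)
    flt <- list(spec = spec, rootEnr = rootEnr, periEnr = periEnr,
                 meja = meja)
    f <- out("flags.tsv")
    writeTsv(data.frame(
      name = members$name, gene_id = members$gene_id,
      specific_to = spec$specific_to,
      root_enriched = members$gene_id %in% rootEnr,
      periderm_enriched = members$gene_id %in% periEnr,
      meja_up = members$gene_id %in% meja), paste0(f, ".partial"))
    finishStage("filters", c(flags = f), cfg$filters)
  })

  # --- prioritize -----------------------------------------------------
  runStage("prioritize", {
    report <- nominate(members, flt$spec, flt$rootEnr, flt$periEnr,
                       flt$meja, subfam,
                       regulatorSubfamilies =
                         cfg$prioritize$regulator_subfamilies,
                       rule = cfg$prioritize$rule)
    f <- out("candidates.tsv")
    writeTsv(report, paste0(f, ".partial"))
    finishStage("prioritize", c(candidates = f),
                list(rule = cfg$prioritize$rule,
                     regulator_subfamilies =
                       as.list(cfg$prioritize$regulator_subfamilies)))
  })

  # --- promoters ------------------------------------------------------
  runStage("promoters", {
    prom <- extractPromoters(genome, models, length = cfg$promoters$length)
    elements <- if (is.null(cfg$inputs$elements))
      readElements(system.file("extdata", "place_elements.tsv",
                               package = "bhlhProspector", mustWork = TRUE))
    else readElements(cfg$inputs$elements)
    hits <- scanElements(prom, elements,
                         bothStrands = cfg$promoters$both_strands)
    f1 <- out("promoters.fasta"); f2 <- out("element_hits.tsv")
    nonEmpty <- prom$sequence != ""
    writeFasta(stats::setNames(prom$sequence[nonEmpty],
                               prom$gene_id[nonEmpty]),
               paste0(f1, ".partial"))
    writeTsv(hits, paste0(f2, ".partial"))
    finishStage("promoters", c(promoters = f1, hits = f2),
                cfg$promoters)
  })

  manifest$parameters <- cfg
  yaml::write_yaml(manifest, out("manifest.yaml"))
  invisible(manifest)
}
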