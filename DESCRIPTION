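Package: bhlhProspector
Title: Genome-Wide bHLH Transcription Factor Family Characterisation and
    Regulator Prioritisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for genome-wide
    characterisation of basic helix-loop-helix (bHLH) transcription factor
    gene families and prioritisation of candidate regulators of root
    secondary metabolism.  Identifies family members in a predicted
    proteome by position-specific scoring matrix (PSSM) domain scanning
    with open-reading-frame validation; computes theoretical isoelectric
    point and molecular weight; derives exon/intron architecture
    statistics (intron phases, symmetric exons, intronless genes); builds
    a neighbour-joining phylogeny of the domain alignment with bootstrap
    supports and clade-based subfamily assignment; scans proteins for
    conserved-motif occurrences; computes RPKM expression, organ/tissue
    specificity and fold-enrichment filters and methyl jasmonate (MeJA)
    response calls; nominates candidate regulators through a configurable
    boolean evidence rule; and extracts promoter regions to scan for
    E-box (CANNTG) and other IUPAC cis-elements.  A fully parameterised
    synthetic-data generator emits a toy genome, annotation, proteome,
    count matrices and ground-truth labels with the statistical structure
    every downstream stage assumes, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    ape,
    phangorn,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
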