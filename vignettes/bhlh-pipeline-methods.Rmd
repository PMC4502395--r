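---
title: "Methods: family identification, structure, phylogeny, expression filtering and promoter scanning"
author: "bhlhProspector"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family identification, structure, phylogeny, expression filtering and promoter scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and procedures the package implements,
the tunable parameters that matter, what the synthetic-data generator does
and does not emulate, and the design choices made where the design was
genuinely open.  It states no empirical result beyond what the test suite
and `scripts/acceptance.R` themselves compute.

## Scope and data model

The pipeline starts from four inputs: a genome FASTA, GFF3 gene models, a
predicted proteome, and integer read-count tables with per-library
metadata (organ/tissue/treatment condition, replicate, total mapped
reads).  Read mapping, transcript assembly and differential-expression
statistics are out of scope — counts are taken as given, and all
expression reasoning is done on RPKM.

Gene models live in a `GeneModels` S4 object wrapping a `GRangesList` of
CDS segments per gene, kept in transcription order.  Coordinates are
1-based closed throughout, the GRanges convention; all length arithmetic
uses `width()`, so GFF3 I/O involves no coordinate shifting and the usual
off-by-one hazards do not arise.  Counts and RPKM matrices are
`SummarizedExperiment`s with the library metadata as `colData`.  One
protein per gene is assumed (no isoform choice).

## Domain detection

The bHLH domain is modelled as an ungapped position-specific scoring
matrix: column counts from a seed alignment, a pseudocount `c` (default
1), frequencies `f(p,a) = (n(p,a)+c)/(n(p)+20c)`, and log2-odds scores
against a background `b(a)` (default uniform 1/20).  Columns that are
majority gap are dropped.  A profile-HMM would model indels better, but an
ungapped PSSM is fully specifiable, fast, and sufficient for a compact
domain; this is a deliberate simplification.

`scanProtein()` slides the PSSM over a protein and keeps the best window;
ties go to the smallest start, with a 1e-9 bit epsilon so that
floating-point summation order cannot flip a tie.  Unknown residues score
0 bits (background-neutral) and are counted in the hit's `n_unknown`.

The default family threshold is a decision procedure, not a number: no
principled universal bit cutoff exists, so `choosePssmThreshold()`
maximises Youden's J between two model-implied distributions — scores of
sequences sampled from the PSSM's own profile (positives) and
*best-window* scores of random background proteins (negatives; a max
statistic, because that is what the classifier thresholds).  It is
deterministic given its seed and needs no labelled data.  Every
identified member must additionally have a valid ORF: length divisible by
3, ATG start, single terminal stop, no internal stop, no ambiguous base.
Members are named `prefix + ordinal` in (contig, start) order so naming
is a pure function of genome coordinates, not of input order.

## Protein properties

Molecular weight is the sum of average (not monoisotopic) residue masses
plus one water — the scale conventional pI/Mw web tools print.  Net
charge at a pH uses Henderson–Hasselbalch over the two termini and the K,
R, H (positive) and D, E, C, Y (negative) side chains.  The default pKa
set is the EMBOSS one (N-term 8.6, C-term 3.6, K 10.8, R 12.5, H 6.5,
D 3.9, E 4.1, C 8.5, Y 10.1); a Bjellqvist-style set is available as
`pkaTable("bjellqvist")`.  pKa-set choice moves a pI by up to roughly
0.2 pH units, which is why published pI values should only ever be
compared at that tolerance.  The pI is found by bisection on [0, 14]
(charge is continuous and strictly decreasing, so the root exists and is
unique) to |Q| < 1e-4 or 200 iterations.  Both quantities are
composition-only; no post-translational modification or disulfide
correction is attempted.

## Gene structure statistics

Intron phase is the cumulative CDS length of the preceding exons modulo
3; phases are computed on CDS only (UTR exons are ignored), and a CDS
whose total length is not a multiple of 3 is an error rather than a
silent truncation, because it signals a broken annotation.  An exon is
symmetric when its two boundary phases agree.  Terminal exons have only
one real boundary, and published symmetric-exon tallies rarely say what
was done with them, so both options are implemented explicitly:

* `terminal_virtual_zero` (default): the missing boundary is assigned the
  virtual phase 0 — the first exon starts at a codon boundary and the
  last must end at one;
* `internal_only`: terminal exons are never symmetric.

`internal_only` always marks a subset of `terminal_virtual_zero`, a
property the suite checks.  Single-exon genes are never symmetric under
either policy.

## Phylogeny and subfamilies

The tree is built from the *detected domain* sequences only, not the full
proteins, so alignment quality is high and the distances reflect the
conserved region.  Pairwise alignment is Needleman–Wunsch with affine
gaps (BLOSUM62, gap open −10, gap extend −1; a gap of length k costs
`open + k·extend`) and a fixed traceback preference
(match/mismatch > gap-in-first > gap-in-second) for determinism.
Multiple alignment is progressive: a guide tree from 3-mer distances
(average linkage) and profile–profile merging with mean-of-pairs column
scores.  Distances are p-distances with pairwise gap deletion; a pair
with zero comparable sites is an error naming the pair.

Neighbour joining follows Saitou–Nei exactly: join the pair minimising
`Q(i,j) = (n−2)d(i,j) − r_i − r_j`, ties to the lexicographically
smallest (representative-leaf) name pair; branch lengths from the
standard formulas, with a negative estimate clamped to zero and the
deficit moved to its sister so the pair's summed length is preserved.
Bootstrap supports resample alignment columns with replacement, rebuild
the tree, and report the percentage of replicates containing each
internal bipartition of the full-data tree; the input is sorted by name
first so supports cannot depend on input order.  The default is 1000
replicates in the pipeline configuration, the conventional figure for
distance trees of this size.

Subfamily labels are assigned in two steps on the midpoint-rooted tree:
anchor leaves (user-supplied known regulators) propagate their label to
the maximal enclosing clade whose internal supports all reach
`min_support` (default 50); remaining leaves are partitioned by cutting
the tree at branch-length depth `max_depth_fraction` (default 0.5) of the
tree height, each hanging subtree becoming one subfamily, labelled A, B,
… in leaf order.  The subfamily count is therefore *emergent* — the
package never forces a particular number of subfamilies, because
published subfamily counts are manual designations that cannot be
reproduced mechanically.  On simulated data the depth cut recovers a
partition that refines the planted domain variants (each subfamily is
variant-pure); it may split a variant into more than one subfamily when
within-variant divergence is comparable to the cut depth.

## Expression filtering

RPKM is `10⁹·C/(N·L)` with `N` the metadata's total mapped reads (not the
column sum, which would silently change under gene subsetting) and `L`
the cDNA length.  Replicates are averaged (arithmetic mean) to condition
level before any filter, the simplest choice consistent with reporting
one value per condition.

* **Detection**: RPKM > 0.
* **Specificity**: detected in exactly one condition of the comparison
  group and exactly zero in the others.  Deliberately no minimum level —
  a gene at RPKM 0.075 in the root and 0 elsewhere is root-specific.
* **Enrichment**: RPKM(target) > `min_rpkm` (default 1, strict) and
  ≥ `fold` (default 2) times *every* other condition in the group; the
  fold comparison is `>=`, so an exact 2-fold gene passes.
* **MeJA response**: `(RPKM(T12)+ε)/(RPKM(T0)+ε) ≥ fold` and
  RPKM(T12) > `min_rpkm`, with pseudocount ε = 0.1 so induction from a
  zero baseline is representable.  How "up-regulated" should be
  thresholded from two libraries is genuinely underdetermined; this fold
  rule is an explicit, configurable stand-in, not a claimed statistical
  test — with one library per time point no replication-based test is
  possible.

Hierarchical clustering for heatmaps uses `log2(RPKM+1)`, correlation
distance (1 − Pearson r) or Euclidean, and average or complete linkage
via `stats::hclust`.  A zero-variance gene has no defined correlation; it
is assigned distance 1 to everything and reported, rather than dropped
silently.

## Candidate nomination

The evidence flags (root-specific, root-enriched, periderm-enriched,
MeJA-up, member-of-regulator-subfamily) are combined by a small boolean
rule grammar (AND/OR/parentheses, no negation — so adding evidence can
never remove a nomination, which the suite checks as a monotonicity
property).  The default rule,

```
(meja_up AND root_enriched) OR (root_specific AND periderm_enriched)
  OR (meja_up AND subfamily_of_known_regulators)
```

encodes the usual prioritisation narrative for a root-periderm,
MeJA-inducible pathway: a candidate regulator should be induced by the
elicitor *and* expressed where the pathway runs.  Because the narrative
is not formal, the rule is data: users can test alternatives by editing a
string.  Wet-lab confirmation (qPCR) is outside the package and only
representable as a user-supplied column.

## Promoters and cis-elements

Promoters are anchored at the translation start (first CDS base) because
CDS-based gene models carry no TSS; this is stated rather than hidden, as
the choice shifts every element position by the 5′ UTR length.  The
default extraction length is 1500 bp, truncated (and flagged) at contig
edges; a gene flush against the edge yields an empty, flagged promoter,
not an error.  Scanning supports full IUPAC patterns on both strands,
with one subtlety: a pattern equal to its own reverse complement (the
E-box `CANNTG` family) is scanned on the forward strand only so each site
is counted once.

## The synthetic-data generator

`simulateGenome()`/`simulateCounts()` emulate the study design the
pipeline targets, with all knobs in `simulationConfig()`:

* **Library design**: 19 libraries — flower/leaf/root/stem × 2
  replicates, periderm/phloem/xylem × 3, and single T0 (carrier) and T12
  (MeJA) leaf libraries.
* **Genes**: default 60 genes on 4 contigs, half carrying a planted
  domain sampled around the seed-PSSM consensus in one of 3 variant
  clusters (the phylogeny ground truth).  Every CDS is a valid ORF by
  construction and is split into 1–12 exons with 60–300 bp introns.
* **Expression classes** planted among the domain-carrying genes:
  organ-specific (hard-zero means outside the home condition, matching
  how "specifically expressed" genes show exact RPKM zeros elsewhere),
  root-/periderm-enriched and MeJA-up with a 4-fold boost, and a
  compound `regulator` class boosted in root *and* after MeJA — without a
  compound class no planted gene could satisfy the default nomination
  rule, which is a conjunction.
* **Counts**: negative binomial, `var = μ + φμ²`, default φ = 0.05
  (typical bulk RNA-seq biological dispersion); φ = 0 gives Poisson.
  Means are `baseline × fold × (L/10³) × (N/10⁶)` with log-normal
  baselines around 50 RPKM and library depths of 8–12 million mapped
  reads — sizes at which a 4-fold planted effect is comfortably above
  counting noise, as real libraries are.
* **Promoters**: intergenic spacers are generated E-box free (occurrences
  are detected and repaired), planted E-boxes are written at recorded
  upstream offsets within 500 bp of the translation start for 60% of
  genes, and spacers are wide enough (1100–1400 bp) that neighbouring
  genes' promoter windows never overlap.  Promoter ground truth is
  therefore exact, not approximate.

What the generator does **not** emulate: 5′/3′ UTRs and TSSs (promoters
anchor at ATG in both generator and scanner, so the tests cannot detect
an anchoring mismatch against real TSS-annotated data); splice isoforms;
sequencing reads (counts are drawn directly); GC or mappability bias;
correlated replicates or batch effects; background E-box occurrences in
promoters (scrubbed to make truth exact, whereas real 1.5 kb promoters
carry ~6 chance E-boxes — so a real analysis must treat E-box presence
as weak evidence, a caveat the scrubbing hides).  Passing tests on this
generator therefore demonstrate correctness of the computations, not
robustness to everything real data can do.

## Determinism and numerical choices

Every stochastic step (simulation, threshold calibration, bootstrap)
takes an explicit seed recorded in the pipeline manifest alongside md5
checksums of every output, and reruns are byte-identical.  Tie-breaks are
specified everywhere ties can occur: smallest window start (with a 1e-9
bit epsilon) in PSSM scans, lexicographic name pairs in NJ joins,
traceback preference order in alignment.  Bisection for pI runs to
|Q| < 1e-4; RPKM conservation holds to floating-point accuracy
(per-library `Σ RPKM·L·N/10⁹` returns the count total).

## Problem sizes in the test suite

The suite exercises: 1000 random gene models against a base-resolution
codon-walk oracle; 200 random additive distance matrices (4–8 taxa) for
exact NJ recovery, with `ape::nj` as an independent cross-check on noisy
matrices; 100 random peptide pairs against an exhaustive alignment
enumeration (plain recursion up to length 6, `Biostrings::pairwiseAlignment`
as the independent reference above that, where enumeration becomes
uneconomical); 200-gene simulations for filter recovery (exact at φ = 0,
sensitivity ≥ 0.9 at default φ for the planted 4-fold effects); and a
full 60-gene pipeline run whose nominated set must equal the planted
regulator class exactly.  These sizes were chosen as the smallest at
which each property is a sharp test rather than a smoke test.

## Known limitations

* The PSSM is ungapped; a domain interrupted by an insertion will score
  as two partial windows and may fall below threshold.
* p-distances saturate for divergent domains; no Poisson or rate
  correction is applied by default (a correction flag would be the first
  extension).
* Subfamily assignment depends on the depth-cut fraction; there is no
  "true" subfamily count and none is claimed.
* The MeJA call from unreplicated T0/T12 libraries is a fold rule, not
  inference.
* Promoter analysis reports element occurrences only; it does not test
  enrichment against a background model.
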