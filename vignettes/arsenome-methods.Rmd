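---
title: "Profiling arsenic-related genes across bacterial genome cohorts: methods and design"
author: "arsenome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling arsenic-related genes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Bacteria carry a recurring repertoire of genes for resisting and
transforming arsenic: cytoplasmic arsenate reduction and arsenite efflux
(the *ars* system: *arsR*, *arsC*, *arsB*/*acr3*, *arsH*, *arsA*, *arsD*,
*arsO*, *glo*, *mfs*), respiratory arsenate reduction (*arrAB*), arsenite
oxidation (*aioABXSRCD*) and arsenite methylation (*arsM*). Because these
families are highly divergent, public genome annotations name them
inconsistently; a similarity-based re-annotation against a curated
reference set is more reliable than trusting product strings. `arsenome`
implements that re-annotation as a reusable, fully tested pipeline for
cohorts of annotated genomes, together with the summaries typically built
on top of it: operon-organization censuses, a core-gene phylogeny to order
strains, a strains-by-families distribution matrix, and habitat-stratified
statistics.

# The procedure

1. **Candidate screening.** Every protein of every genome is aligned
   (Smith–Waterman, BLOSUM62, affine gaps 11/1) against curated exemplars
   of the 20 gene families. A hit passes with E-value ≤ 1e-10, coverage
   ≥ 70% and identity ≥ 35% (all inclusive); the best passing hit assigns
   the family. E-values use Karlin–Altschul statistics
   (E = *K·m·n·e^(−λS)*, λ = 0.267, K = 0.041, the standard gapped
   BLOSUM62/11/1 parameters) — the screen thresholds are on derived
   metrics, so an exact aligner behind them is a faithful stand-in for a
   heuristic search tool.
2. **Cross-family noise filter.** A candidate whose best family score is
   not at least 1.1× the best score of any other family is rejected as
   ambiguous. This replaces a manual functional-classification step with a
   deterministic rule; the margin only matters for genuinely multi-domain
   or chimeric proteins, which are flagged rather than silently counted
   twice.
3. **Ortholog clustering.** A cohort-wide all-vs-all similarity graph
   (edge iff the screen passes in at least one direction; weight
   min(−log10 E, 200)) is clustered with Markov clustering (MCL) at
   inflation 1.5.
4. **Clustered/scattered partition.** Arsenic candidates that lie in a
   gene-neighborhood cluster (two or more candidates with at most one
   intervening non-arsenic gene and at most 5 kb between neighbors, never
   across contigs) are accepted outright; isolated ("scattered")
   candidates are re-searched against the clustered genes of their own
   family cohort-wide and confirmed only on a passing hit — clustered
   context is treated as the ground truth that scattered singletons must
   corroborate. If a cohort has no clustered genes at all the scattered
   set falls back to its reference-database best hits, with a warning.
5. **Operon forms.** Each cluster is named by its gene order read in the
   transcription direction of its majority strand (ties: the
   lexicographically smaller reading), so a mirrored copy of an operon
   receives the same canonical form (e.g. `arsR-arsC-acr3` whichever
   strand carries it). Forms above 4.5% of counted operons are "main"
   forms.
6. **Core-gene phylogeny.** A second all-vs-all at identity ≥ 50% feeds
   MCL; groups with exactly one member per genome and member lengths
   within ±10% of the group median are the single-copy core. Each group is
   aligned with the built-in progressive aligner, alignments are
   concatenated, and a neighbor-joining tree is built on Poisson-corrected
   distances (d = −ln(1−p), gapped columns excluded pairwise) with
   bootstrap support from column resampling within partitions.
7. **Distribution matrix and habitat statistics.** A strains × (20
   families + 1 ars-cluster-count) matrix, rows in ladderized tree order,
   flags strains at ≥2× / ≥4× the cohort-average gene total (the
   single/double asterisk of the heatmap); habitat summaries compare
   host-associated (H, P, Z) with environmental (S, W, D, R) strains and
   arsenic-rich with other strains, and a Pearson correlation (two-sided
   t-test) relates genome size to gene count.

# Parameters that matter

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| screen max E-value | 1e-10 | expected chance hits | conventional screening cutoff |
| screen min coverage | 70 | % of query | rejects short local matches |
| screen min identity | 35 (annotation), 50 (core) | % of aligned columns | family membership vs strict orthology |
| coverage side | query | — | the genome protein is the query; configurable (`coverageOn`) because the choice of denominator is a convention, not a law |
| gap penalties | 11 open, 1 extend | score units | standard gapped BLOSUM62 search |
| MCL inflation | 1.5 | — | granularity typical for ortholog inference |
| MCL convergence | max-norm < 1e-6, ≤ 100 iterations, prune < 1e-12 | — | standard MCL practice; bounded runtime; non-convergence is an error, not a silent result |
| neighborhood | ≤ 1 intervening gene, ≤ 5 kb gap | genes, bp | tolerates one inserted ORF (e.g. *glo*/*mfs* members inside *ars* operons) while excluding coincidental co-residence |
| main-form threshold | 0.045 | fraction of operons | the "five main forms" convention |
| core length tolerance | ±10% of median | fraction | "nearly identical lengths" needs a number; 10% is permissive for indel-free core genes |
| bootstrap replicates | 100 (tests), 1000 (publication) | replicates | support stabilizes long before 1000 at these matrix widths |

Identity is counted over aligned columns with gaps in the denominator (as
a BLAST-style percent identity); coverage is the aligned fraction of the
query. k-mer prefiltering (shared 4-mers) skips pairs that cannot pass the
screen; the all-vs-all for the core screen requires 3 shared 4-mers, since
pairs at ≥ 50% identity share dozens while unrelated proteins of this
length share about half a 4-mer on average.

# What the synthetic cohort emulates

`defaultCohortPlans()` builds 12 strains spanning all ten habitat codes
(H, P, Z, R, S, D, W, E, U, NA):

- two arsenic-rich strains (soil, wastewater) carrying more than four
  times the cohort-average arsenic gene count, so the double-asterisk
  flag and the rich-vs-other comparison are exercised end to end;
- the five most frequent *ars* operon organizations (`arsC-acr3`,
  `arsR-arsC-acr3`, `arsR-arsC-acr3-arsH`, `arsR-glo-arsC-acr3`,
  `arsR-arsC-acr3-arsC-arsH`) plus *arsD-arsA-arsB-arsC*, *aio* operons
  flanked by the *pstSCAB* phosphate transporter, a single *arrAB*
  strain, and an *arsR-arsM* cluster;
- strains with no arsenic genes at all, strains with only scattered
  genes, and a draft-like two-contig genome;
- ten universal single-copy core genes (at ~85% identity to a shared
  ancestor per strain, hence ≥ 70% between strains) in every genome;
- random background/decoy proteins (length 150–450) that are guaranteed
  free of 8-mer word matches to any planted ancestor, and optional
  near-miss decoys (family members mutated to ~25% identity — inside the
  25–30% band, at the low end so that local-alignment identity stays
  clearly below the 35% screen) to exercise the threshold boundary.

Every planted feature is recorded in a truth table (per-family counts,
cluster members and canonical forms, scattered genes, the core-gene map),
so precision and recall of the whole pipeline are measurable exactly.

**What it does not emulate.** Sequences are random proteins with
controlled mutation distances: there is no real domain structure, no
compositional bias, no low-complexity regions, no shared folds between
families, and no horizontal-transfer history. Passing tests therefore
demonstrate that the machinery is correct (screening thresholds behave,
neighborhoods are detected, forms canonicalize, core genes concatenate,
counts conserve) — not that the thresholds themselves are optimal for
real proteomes, where cross-family structural similarity makes the 35%
boundary genuinely fuzzy.

# Numerical and design choices

- **"1-e^10" is read as 1e-10.** The conventional E-value cutoff; the
  config documents the reading rather than hard-coding it silently.
- **Exact alignment, not a heuristic.** At cohort scales of hundreds of
  genomes an exact Smith–Waterman behind a k-mer prefilter is affordable
  and removes an external binary; scores are checked against an
  independent full-matrix DP oracle in the tests.
- **MCL self-loops.** A unit self-loop is added to every node before
  column normalization — the standard regularization that prevents
  period-2 oscillation on bipartite-like graphs. Clustering runs per
  connected component (a mathematical no-op that bounds matrix sizes),
  with vertices sorted by name first so results are invariant to input
  order.
- **Canonical form rule.** Reading direction follows the majority strand
  of the cluster (strand ties: lexicographically smaller reading). A
  naive "lexicographically smaller of forward/reverse" rule would rename
  `arsR-arsC-acr3` to its reversal and diverge from the field's customary
  regulator-first form names.
- **Cluster pathway.** A cluster is counted in the *ars* census iff the
  majority of its members belong to the *ars* pathway (ties resolved in
  the order ars, aio, arr, arsM). Mixed clusters (e.g. *arsR-arsM*) are
  counted once, not once per pathway.
- **Ties in best-hit selection** go to the higher raw score, then the
  lexicographically smaller subject id — determinism over elegance.
- **NJ instead of ML.** The tree's only downstream role is ordering
  heatmap rows; NJ on Poisson-corrected distances is deterministic,
  seconds-fast, and recovers the generating topology in ≥95% of
  simulated replicates at ≥50 mutations/edge (checked in the acceptance
  suite). The module boundary (`buildTree`) is pluggable if an external
  ML tool is preferred.
- **Negative NJ branch lengths are clamped to zero**; saturated distances
  (p ≥ 1) are an error for the main tree and are capped at p = 0.95 only
  inside bootstrap replicates, where a rare saturated resample should not
  abort the run.
- **Ladderization** is fixed (ascending clade size, larger clade last) so
  the row order of the matrix is reproducible.
- **Flag thresholds are inclusive** (≥ 2×, ≥ 4× the mean): "two times as
  many" is read as at-least.
- **Host/environment sets.** H, P, Z vs S, W, D, R; E (endosymbionts),
  U (miscellaneous) and NA are summarized but excluded from the
  comparison. Whether rhizosphere (R) counts as environmental is a
  judgment call; the sets are arguments of `summarizeByGroup`.
- **Degenerate inputs.** Empty candidate lists, all-zero matrix rows,
  single-sequence "alignments", empty habitat groups and clusters at
  contig edges are all defined results (empty table, retained zero row,
  warning + identity, omitted column with a message, truncated flank
  list), not errors.

# Problem sizes

The shipped study cohort is 12 strains × ~50 genes (≈ 630 proteins,
including ten core genes per genome); a full pipeline run, including the
all-vs-all screens, MCL, ten progressive alignments, a 100-replicate
bootstrap and all reports, takes on the order of three minutes on one
CPU. The statistical-recovery checks use n = 200 observations × 100
replicates (Pearson) and 8 taxa × 2000 sites × 50 replicates (NJ). These
sizes were chosen as the smallest that exercise every code path with
comfortable statistical margins.

# Known limitations

- Reference exemplars are synthetic stand-ins generated around random
  family ancestors; for real cohorts, users must supply a curated FASTA
  (`ref|<family>|<i>` ids) gathered from a protein database.
- The neighborhood rule (≤1 intervening gene, ≤5 kb) is a reasonable
  operationalization of "genes gathered together", but no published
  operon count is available to validate it against; both knobs are
  exposed.
- Draft genomes can split a cluster across contigs; the pipeline never
  merges across contigs and instead leaves such fragments as separate
  clusters (or scattered genes), which slightly inflates form diversity
  on fragmented assemblies.
- The COG-style functional filter is approximated by the 1.1×
  best-family margin; no external orthology database is consulted.
- Habitat comparisons are descriptive means; no phylogenetic comparative
  correction is applied.
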