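---
title: "Subsample-ensemble discovery of shared promoter motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subsample-ensemble discovery of shared promoter motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

When a treatment — here, nitrogen supplementation of field-grown potato —
changes the expression of a set of genes consistently across cultivars and
sampling dates, a natural hypothesis is that those genes share upstream
*cis*-regulatory elements. `promens` implements the full inference chain
for that hypothesis at the promoter level:

1. intersect per-condition differential-expression (DE) tables into
   consensus over- and under-expressed gene lists;
2. extract the 1000 bp upstream flanking region of every gene
   (strand-aware, TSS-anchored);
3. build a genome-wide k-mer background model from all upstream regions;
4. discover over-represented motifs *de novo* in many small random subsets
   of the responsive promoters;
5. collapse the redundant pool of subset-level motifs by k-medoids
   clustering of position weight matrices (PWMs) and represent each
   cluster by its average;
6. map the cluster averages back onto the promoters (both strands,
   TSS-relative coordinates) and annotate them against a database of IUPAC
   consensus motifs.

Every stage is exposed as an ordinary R function, and a synthetic-data
module (`sample_background_sequences()`, `plant_motifs()`,
`simulate_de_tables()`, `make_database_fixture()`) generates all four
input types with known ground truth, so the whole chain can be exercised
and scored at desk scale.

## Why subsample ensembles

A motif carried by only a fraction of the responsive promoters is easy to
miss when discovery runs once on the pooled set: the signal is diluted by
the promoters that lack it. Running discovery independently on many small
random subsets (the classic design is 5000 subsets of 10 promoters per
gene list, the package defaults in `make_subsets()`) gives each run a
chance to draw a subset enriched for the carriers. The price is massive
redundancy — the same motif is rediscovered across subsets — which is
exactly what the clustering stage resolves.

The subsets are independent draws (a promoter may appear in many
subsets): sampling 5000 subsets of 10 from a few dozen genes forces
overlap, and within-subset sampling is without replacement.

## The discovery statistic

Genome-scale workflows of this kind delegate discovery to three external engines
with different algorithmic styles, each gated by its own native
significance rule. `promens` keeps the three roles and the three gates
but defines its statistics explicitly so every number is reproducible and
oracle-checkable:

* **`seed_qvalue`** — every word of width 6 to `w_max` (both strands,
  reverse-complement pairs collapsed to a canonical form) is counted by
  the number of subset sequences containing it (`seq_hits`). Under the
  background model the per-sequence presence probability is
  `p1 = 1 - (1 - p_word)^(L - w + 1)` with `p_word` the two-strand word
  probability, and the p-value is the binomial upper tail
  `P(X >= seq_hits | n, p1)`. Benjamini–Hochberg correction is applied
  across all candidates of the run and words with `q <= 0.05` are
  returned as PWMs built from their matching instances.
* **`ranked_topk`** — the same statistic, but returning the top 5 words
  by p-value regardless of an absolute threshold (rank-based gating).
* **`em_refine`** — seed words are polished by a ZOOPS-style EM over the
  subset (at most 20 iterations or a log likelihood-ratio improvement
  below 1e-4, for determinism), and a refined motif is kept when its
  seed-count-corrected score is at most 0.001 (an e-value-like gate).

The minimum motif width is 6 bp and all engines search both strands;
these two constraints are enforced in `engine_config()`.

Two approximations matter. The per-sequence presence probability treats
window matches as independent, which slightly overestimates `p1` for
self-overlapping words — a conservative direction. And BH is applied
within each subset run, not pooled across the ensemble; the ensemble's
protection against noise comes from clustering (isolated false positives
do not form consistent clusters) rather than from a global correction.

## Background model

`build_background()` counts every N-free window of length 1..K (default
K = 3) over all upstream regions, on the given strand only — discovery
handles reverse complements explicitly, and single-strand counting avoids
double-counting palindromes. Word probabilities beyond K use the
order-(K-1) Markov chain factorisation. The same model drives synthetic
promoter generation, so null calibrations are exact by construction.

## Clustering and cluster averages

`motif_distance()` is the metric under the clustering: the minimum over
all ungapped offsets with at least 4 overlapping columns, and over both
orientations of the second motif, of the mean per-overlapping-column
Euclidean distance between column distributions. The legacy motif-toolkit
metrics this stage traditionally relies on are unpublished, so this
package defines its own, documents it, and keeps it configurable through
`min_overlap`.

`cluster_motifs_kmedoids()` is a Voronoi-style alternation (assign to the
nearest medoid, re-pick each medoid as the member minimising within-
cluster cost) over seeded restarts, keeping the best cost. The number of
clusters defaults to `"auto"`: a sweep of k = 2..min(20, n-1) scored by
mean silhouette width, because no k is prescribed by the study design.
`restarts = "exhaustive"` refines from every initial medoid set and is
how the package's tests verify agreement with the brute-force optimum at
small n. The implementation is in-package rather than delegated because
the exhaustive-initialisation mode and the motif-specific distance are
both needed; the silhouette itself comes from the `cluster` package.

`average_cluster()` aligns every member to the medoid at its best
offset/orientation, averages columns position-wise over the members
covering each position, trims positions covered by fewer than half the
members, and renormalises. The consensus of the average uses a
three-tier IUPAC notation: an uppercase base when the top probability is
at least 0.7, a lowercase two-base code (r/y/s/w/k/m) when the top two
sum to at least 0.8, and `.` otherwise. The 0.7/0.8 thresholds are this
package's choice, made to reproduce the uppercase/lowercase/dot notation
style of published consensus tables; both are arguments of
`consensus_string()`.

## Mapping and annotation

`scan_regions()` scores every window on both strands by log2-odds against
the order-0 background and reports positions reaching a fraction
(default 0.85) of the motif's maximum achievable score. The threshold is
expressed as a score fraction because classical site-mapping tools do not
publish their cutoffs; `score_fraction = 1` with a point-mass PWM
degenerates to exact word matching. Offsets are TSS-relative and
negative, with the TSS at the right end of each region (an instance
abutting the TSS has offset `-width`); file exports use region-relative
BED-like coordinates.

`match_database()` compares IUPAC consensi over all ungapped alignments
with at least 4 overlapping positions and both orientations, counting
positions whose base sets do not intersect. Ties prefer the larger
overlap, so a full-width one-mismatch alignment beats a short accidental
exact overlap.

## DE consensus

`consensus_gene_lists()` calls a gene over-expressed when it is
significant with a positive log2 fold change in *every* (cultivar,
timepoint) cell, and under-expressed symmetrically — direction
consistency is required by default because the upstream workflow keeps
separate over/under lists; `require_direction = FALSE` relaxes it. A
table's own significance flag takes precedence when present; otherwise
`q <= alpha` (default 0.05) is used. Genes absent from one table are
treated as non-significant there rather than erroring, since DE callers
drop untestable genes. Genes significant in all cultivars at exactly one
timepoint are tallied separately per timepoint and direction — the class
reported in condition-specific counts.

`normalize_by_housekeeping()` and `rank_correlation()` support the
orthogonal-platform validation step: counts are rescaled so the
housekeeping geometric mean is equal across samples, and agreement
between platforms is summarised by Spearman's rank correlation
(average ranks for ties; constant vectors are an error because the
statistic is undefined).

## Coordinate conventions and degenerate inputs

All internal coordinates are 0-based half-open; GFF3 (1-based closed) is
converted at the boundary: a "+" gene's TSS is `start - 1`, a "-" gene's
is `end - 1`. The extracted sequence always reads 5'->3' on the gene's
strand and never includes the TSS base itself. Regions truncated by a
contig edge are kept at their true length (a `min_length` argument allows
stricter policies); zero-length regions are dropped with a warning.
Overlapping gene models are extracted independently. Windows containing
N are excluded from background counts, word matching, and scanning.

## What the synthetic data does and does not emulate

The generator produces promoters from the fitted background model with
motif instances *overwritten* (not inserted) at uniform non-overlapping
offsets, on either strand — so region lengths and coordinates stay
comparable and ground truth is exact. DE tables place designated genes
in the consistent, timepoint-specific, or null classes with configurable
effect size (default mean |log2FC| = 2, sd 0.4, q uniform below/above
alpha). What this does **not** emulate: real promoter composition
(CpG/TA structure, repeats, nucleosome signals), correlated motif
co-occurrence, dependence between DE cells, or read-level noise.
Passing the planted-recovery tests therefore demonstrates the inference
machinery is correct and calibrated under its own model, not that the
biological discovery rate on real genomes matches.

## Problem sizes in the test-suite and acceptance runs

The packaged checks run the full chain at desk scale: 60 promoters of
1000 bp with an 8-bp motif planted in 30% of them, ensembles of 300
subsets of 10 over 10 seeded replicates; null calibration on 500
background-only subsets; end-to-end pipeline runs on a 30-gene synthetic
genome with 15 subsets of 8 per direction. These sizes were chosen so a
complete run finishes in minutes on a laptop while keeping every rate
estimate's sampling error well below the asserted margins; the
study-scale defaults (5000 x 10) remain the package defaults.

## Known limitations

* Word enumeration with `max_mismatches > 0` is quadratic in candidates
  times windows and intended for small inputs; the default exact-word
  mode is the fast path.
* The EM engine refines single-block (ungapped) motifs only; gapped or
  two-part elements are out of scope.
* Database matching is consensus-string based; PWM-to-PWM comparison is
  available through `motif_distance()` but no match significance is
  computed.
* Transcript-level TSS inference, promoter prediction, and repeat
  masking are out of scope: the annotation's gene coordinates are taken
  as ground truth.
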