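# promens

Subsample-ensemble *de novo* motif discovery in upstream regulatory
regions.

## What it is for

Expression studies that compare treatments across several cultivars and
sampling dates (for example, nitrogen supplementation of field-grown
potato) often end with a short list of genes that respond consistently in
every condition. `promens` takes the analysis from that point to shared
*cis*-regulatory hypotheses:

* **DE consensus** — intersect per-(cultivar, timepoint)
  differential-expression tables (CuffDiff-style flat files) into
  consensus over- and under-expressed gene lists, with a separate tally
  of genes significant at only one timepoint.
* **Upstream regions** — extract the 1000 bp upstream flanking region of
  every annotated gene from FASTA + GFF3, strand-aware and TSS-anchored,
  and build a genome-wide k-mer background model from all of them.
* **Ensemble discovery** — run word-based motif discovery on thousands of
  small random promoter subsets (defaults: 5000 subsets of 10). Each
  engine gates its output by a classical rule: Benjamini–Hochberg
  `q <= 0.05`, top-5 ranking, or an e-value-like EM score `<= 0.001`;
  minimum motif width 6 bp, both strands.
* **Redundancy resolution** — cluster the pooled motifs by k-medoids
  under a PWM alignment distance and represent each cluster by its
  average PWM with a three-tier IUPAC consensus (`A` / `r` / `.`).
* **Mapping and annotation** — scan the cluster averages back over the
  responsive promoters (log-odds, both strands, TSS-relative offsets) and
  rank matches against a flat-file database of IUPAC consensus motifs by
  minimal mismatch count over all ungapped alignments.
* **Synthetic data** — generate all of the above inputs with known ground
  truth (background-sampled promoters, planted motif instances, DE grids
  with designated responsive genes, perturbed databases), so the whole
  chain is testable end to end.

The statistical core for a word of width `w` observed in `s` of `n`
subset sequences of length `L` is the binomial upper tail

    p = P(X >= s),  X ~ Binomial(n, p1),
    p1 = 1 - (1 - p_word)^(L - w + 1),

with `p_word` the two-strand word probability under an order-K Markov
background, followed by BH correction across the candidate words of the
run.

## Worked example

Plant an 8-bp motif in 30% of 60 synthetic kilobase promoters, recover it
with an ensemble of subsets, and annotate it:

```r
library(promens)

bg  <- build_background(strrep("ACGT", 2500), max_order = 1)
prom <- sample_background_sequences(bg, n = 60, length = 1000, seed = 1)
pl  <- plant_motifs(prom, planted_motif_spec("ACGTCAGT", prevalence = 0.3,
                                             seed = 2))

coll   <- make_subsets(pl$regions$gene_id, n_subsets = 300,
                       subset_size = 10, seed = 3)
motifs <- run_ensemble(pl$regions, coll, bg,
                       engine_config("seed_qvalue", width_range = c(6, 8)))
length(motifs)
#> [1] 50

clusters <- cluster_motifs_kmedoids(motifs, k = "auto", seed = 4)
cluster_report(clusters)
#>   cluster_id n_members medoid_consensus average_consensus total_within_cost
#> 1 cluster_01        23         ACGTCAGT          ACGTCAGT         0.7759362
#> 2 cluster_02         7         CGGAAGTC           GAwGTC.         1.3954982
#> 3 cluster_03         7         GTAAAGCA          GTAAAkCA         1.0930373
#> 4 cluster_04         8         CTCGATGC          TCGCTCG.         1.1230619
#> 5 cluster_05         5         CCTGAGTA           ...CCTG         0.3602984

match_database(clusters[[1]]$average,
               data.frame(id = c("S1F", "X1"),
                          consensus = c("TACCAT", "ACGTCAGA"),
                          keywords = ""),
               min_overlap = 6)
#>   query_motif_id database_id mismatches best_offset orientation overlap
#> 1       ACGTCAGT          X1          1           0           +       8
#> 2       ACGTCAGT         S1F          3           0           -       6
#>   keywords rank
#> 1             1
#> 2             2
```

The largest cluster's average consensus equals the planted word
`ACGTCAGT` exactly (the other clusters are the expected handful of
background false positives, each supported by far fewer subsets); the
database entry one substitution away ranks first with `mismatches = 1` —
the same computation that, on the real data, pairs a discovered motif
such as `TACCAC` with the S1F binding site `TACCAT`.

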