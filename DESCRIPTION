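Package: promens
Title: Subsample-Ensemble De Novo Motif Discovery in Upstream Regulatory Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers shared upstream regulatory motifs for sets of
    co-regulated genes, following a nitrogen-response expression study
    design. Intersects per-condition differential-expression tables into
    consensus responsive gene lists, extracts 1000 bp upstream flanking
    regions with strand handling, builds genome-wide k-mer background
    models, discovers over-represented motifs de novo in ensembles of
    small random promoter subsets, resolves redundancy by k-medoids
    clustering of position weight matrices, maps cluster-average motifs
    back onto promoters, and annotates them against IUPAC consensus motif
    databases. A synthetic-data module generates promoters with planted
    motifs and differential-expression fixtures with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    cluster,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
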