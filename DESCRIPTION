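Package: funlnc
Title: Functional lncRNA Prediction from Multi-Omic Regulatory Networks
Version: 0.1.0
Authors@R:
    person("funlnc", "developers", email = "funlnc@example.org",
           role = c("aut", "cre"))
Description: Builds upstream (epi)genetic and downstream post-transcriptional
    regulatory networks for long noncoding RNAs from interval-level genomic
    data (ChIP-seq peaks, histone marks, methylation sites, SNPs, enhancer
    and super-enhancer calls, chromatin accessibility regions, 3D chromatin
    interaction anchors and curated target tables), derives a 57-column
    three-category feature matrix per lncRNA, classifies functional versus
    nonfunctional lncRNAs with a random-forest model trained under
    group-aware splits, and prioritizes high-confidence functional lncRNAs
    with an empirical random-permutation score. Ships a synthetic-data
    generator so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
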