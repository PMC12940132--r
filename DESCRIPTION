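Package: bgctempo
Title: Temporal Dynamics and Transplant Engraftment of Biosynthetic Gene
    Clusters in the Gut Microbiome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for tracking biosynthetic gene clusters (BGCs) in
    longitudinal shotgun-metagenomic cohorts: catalog dereplication with
    MinHash sketches and Markov (MCL) graph clustering, coverage-breadth
    presence calling with grid-search cutoff optimization against mock
    communities, RPKM abundance, per-cluster two-state Markov turnover
    models that separate persistent from transient clusters, donor to
    recipient colonization statistics for fecal microbiota transplantation
    (FMT) triads, and hypergeometric enrichment of functional annotations.
    A synthetic-data module generates every pipeline input with planted
    ground truth so each stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
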