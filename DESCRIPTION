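Package: endomicro
Title: Low-Biomass Endometrial Microbiome Profiling and Outcome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis pipeline for low-biomass endometrial 16S rRNA
    genus-level profiles. Provides biomass-detectability quality control against
    blank controls, blank-prevalence contaminant identification, dual
    abundance-prevalence taxon filtering with kitome exclusion, centred log-ratio
    (clr) transformation with run-robust z-scoring, outcome-stratified microbial
    co-occurrence networks with Louvain communities, live-birth-anchored taxon
    reference ranges with out-of-range distance tests (including a chronic
    endometritis pathogen screen), and a per-outcome Bayesian normal model of the
    Lactobacillus-minus-other-taxa statistic with highest posterior density
    intervals and posterior predictive draws. A Dirichlet-multinomial cohort
    simulator with realistic read-accounting metrics makes every stage testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
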