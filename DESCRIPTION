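Package: ibsmomics
Title: Microbiome-Metabolome Integration for Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrated analysis of gut metagenomic and untargeted
    metabolomic profiles from case-control cohorts such as irritable bowel
    syndrome (IBS) studies. Implements differential-feature identification
    combining Wilcoxon rank-sum tests, Benjamini-Hochberg false discovery
    rates, fold changes and a from-scratch PLS-DA variable importance in
    projection (VIP) score; residual-based greedy covariation clustering of
    differential metabolites; microbe-metabolite Spearman association with a
    control-cohort replication filter; Bray-Curtis/PERMANOVA factor
    screening; and random-forest marker selection via averaged
    cross-validation error curves with a minimum-plus-standard-error cutoff.
    A synthetic-cohort generator with known ground truth (planted
    differentials, covariation clusters and species-metabolite couplings)
    drives testing and parameter-recovery benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
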