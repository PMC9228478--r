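Package: twinmetab
Title: Twin-Based Heritability Analysis of Urinary Metabolomics Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for estimating the heritability of urinary
    metabolites in twin cohorts. Provides a synthetic-data generator for twin
    families with known additive (A), dominant (D), common-environmental (C)
    and unique-environmental (E) variance structure plus realistic nuisance
    layers (creatinine dilution, limit-of-detection censoring, item
    missingness, pooled-QC injections); quality-control driven preprocessing
    (RSDqc filtering, below-LOD imputation, creatinine normalization, inverse
    normal rank transformation); family-clustered linear mixed models for sex
    and age with Benjamini-Hochberg FDR control and discovery-replication
    concordance; and classical-twin-design variance decomposition (ACE/ADE)
    by full-information maximum likelihood with profile-likelihood confidence
    intervals, MZ-correlation reliability banding and per-platform summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
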