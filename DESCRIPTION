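Package: triodnm
Title: Trio-Based De Novo Mutation Detection and Rate Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate de novo mutations (DNMs) in parent-offspring
    trio exome data as Mendelian violations, applies genotype-quality, read-depth
    and allele-balance filters, models per-site callable probabilities from a
    genotype-likelihood read model, and estimates the per-position-per-generation
    germline mutation rate with Wilson score confidence intervals. Includes
    mutation-spectrum summaries (Ts/Tv, per-chromosome distributions), stratified
    rates and linear-regression models over binary genomic-context annotations
    (DNase hypersensitivity, CpG islands, histone marks, conservation, expression
    specificity), multi-predictor pathogenicity vote aggregation, and a synthetic
    trio-exome simulator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    IRanges,
    vcfR,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
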