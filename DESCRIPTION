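Package: kinfit
Title: Mechanistic Parameterization of Kinomic Peptide-Array Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits mechanistic kinetic models to per-peptide fluorescence time
    series from kinome peptide arrays (144-peptide chips read over reaction
    cycles). Three candidate progress-curve models are supported: a simple
    negative exponential, a background-corrected negative exponential, and a
    background-corrected rational hyperbolic whose parameters are an initial
    phosphorylation rate and an asymptotic capacity. Fitting uses a
    coordinate-wise adaptive-step least-squares search; goodness of fit is
    assessed with R-squared and an exact Wald-Wolfowitz runs test on residual
    signs, which also drives the quality-control gate. Replicate
    reproducibility of fitted parameters is summarised with quantile-quantile
    rank correlations and rule-of-thumb kernel density estimates. A seeded
    synthetic-chip generator with known ground truth supports validation
    without instrument data, and a small command-line interface exposes the
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
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
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
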