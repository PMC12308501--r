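Package: plinet
Title: Phase-Lag-Index Connectivity and Small-World Network Analysis for
    Band-Limited ROI Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for functional-network analysis of
    source-level neurophysiological recordings: band-pass filtering into
    canonical frequency bands, fixed-length epoching with an epoch-count
    quality gate, Hilbert instantaneous phase, phase lag index (PLI)
    connectivity matrices, proportional-threshold binarization, clustering
    coefficient, characteristic path length with finite-distance averaging,
    small-worldness normalized against degree-preserving rewired null
    networks, and the downstream statistical models (condition-by-diagnosis
    mixed-effects models, change-score versus trait regressions with robust
    standard errors, and baseline-dependence regressions). Includes a
    synthetic-data module that simulates cohorts and phase-coupled ROI time
    series with known ground truth so the whole pipeline is testable without
    access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lme4,
    lmtest,
    patchwork,
    purrr,
    Rcpp,
    readr,
    rlang,
    sandwich,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    broom,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
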