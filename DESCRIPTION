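Package: cscgp
Title: Genetic-Programming Forecasts of Cancer Stem Cell Marker Dynamics
    Under Chemotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates and models the enrichment of drug-resistant cancer
    stem cell (CSC) subpopulations under 5-fluorouracil treatment as measured
    by flow cytometry. Provides a two-compartment exponential-kill model of
    differential drug-induced death that generates percent-positive marker
    time series, an event-level flow-cytometry simulator with log-normal
    scatter and fluorescence mixtures, threshold gating of events into
    marker-signature percentages, a from-scratch genetic-programming symbolic
    regressor over protected-operator expression trees, and a forecasting
    layer that fits each marker series on early time points, validates on a
    held-out later point, and extrapolates to a follow-up time with R-squared
    scoring. Includes group-comparison statistics (Shapiro-Wilk screen, then
    t or Mann-Whitney tests) and a reproducible end-to-end study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
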