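Package: dsfusion
Title: Bayesian Downscaler Fusion of Monitor and Gridded Air Quality Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits the Downscaler model, a Bayesian spatial regression that
    fuses point-level PM2.5 monitor observations with gridded chemical
    transport model (CTM) output to produce daily concentration surfaces
    with uncertainty. Includes a synthetic-data generator emulating an
    urban monitoring network with mixed sampling frequencies and a remote
    network on a shared 1-in-3-day schedule, per-day Gibbs sampling with
    conjugate priors and grid-search decay parameters, paired
    baseline/augmented network scenarios with annual, quarterly and 98th
    percentile aggregation and difference surfaces, and withholding-based
    cross-validation reporting bias, mean squared error and prediction
    interval coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    tibble,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
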