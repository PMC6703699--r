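Package: sinadapt
Title: Generative and Phenomenological Models of Sinusoidal Saccade
    Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trial-by-trial modeling of saccadic gain adaptation
    driven by a sinusoidal intra-saccadic target step. Builds per-trial
    stimulus series for the sinusoidal double-step paradigm, forward-simulates
    a sixteen-member family of noise-free linear time-invariant state-equation
    learners (delta rule with retention, drift, and double error sampling),
    provides the closed-form mapping from generative parameters to the
    phenomenological description (periodic amplitude and lag, baseline
    asymptote and timescale), fits both model classes to gain series with
    Akaike-weight model selection and decibel-scale Bayesian evidence, and
    generates seeded synthetic cohorts for parameter-recovery and
    model-selection validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    lhs,
    minpack.lm,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
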