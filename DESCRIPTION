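Package: survgp
Title: Genetic Programming for Discrete-Time Survival Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automatic development of clinical prediction models for
    right-censored survival data by tree-based genetic programming.
    Survival records are expanded to the person-period (counting-process)
    format, a logistic link maps an evolved log-odds expression to
    discrete-time hazards, and the censored-data negative log-likelihood
    serves as the fitness function for steady-state symbolic regression.
    Includes a linear discrete-time hazard baseline, censoring-aware
    evaluation (truncated Harrell's C-statistic, calibration groups with a
    generalized Hosmer-Lemeshow chi-square, model-versus-Kaplan-Meier
    survival curves), and a synthetic cohort generator that emulates a
    secondary-prevention cardiovascular cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
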