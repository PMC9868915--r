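Package: instmfa
Title: Isotopically Non-Stationary Metabolic Flux Analysis of 13C Labelling Time-Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for isotopically non-stationary metabolic flux analysis
    (INST-MFA) of 13C labelling experiments in compartmented metabolic
    networks, aimed at heterotrophic plant cell cultures and similar systems.
    Provides a plain-text atom-transition model format, elementary metabolite
    unit (EMU) decomposition and simulation of mass-isotopologue-distribution
    time-courses, natural-abundance correction and related measurement
    processing, multistart Levenberg-Marquardt estimation of fluxes and pool
    sizes under a variance-weighted least-squares objective with chi-squared
    acceptance, parameter uncertainty by profile-likelihood continuation and
    Monte Carlo resampling with confidence-interval overlap significance
    rules, PCA and PLS-DA over flux ensembles, and a synthetic-experiment
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    pracma,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
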