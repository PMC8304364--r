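Package: ppdmarkov
Title: Three-State Continuous-Time Markov Models for Postpartum Depression
    Screening Panels
Version: 0.1.0
Authors@R: person("Panel", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fits time-homogeneous three-state continuous-time Markov models
    to panel-observed postpartum depression (PPD) screening data, where
    severity states are derived from Edinburgh Postnatal Depression Scale
    (EPDS) scores observed at a handful of postpartum visits. Provides the
    panel-data (Kalbfleisch-Lawless) likelihood with proportional-intensity
    covariate effects, maximum-likelihood estimation with asymptotic
    inference, and the derived quantities used in screening-interval
    planning: embedded jump-chain probabilities, mean sojourn times,
    interval transition probabilities with bootstrap confidence intervals,
    stationary occupancy, and per-transition covariate hazard ratios. A
    synthetic cohort generator emulates the three-visit study design so the
    whole pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
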