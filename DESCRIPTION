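Package: gentacool
Title: Population Pharmacokinetics of Gentamicin in Cooled Asphyxiated Neonates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements an allometrically scaled two-compartment population
    pharmacokinetic model for gentamicin in (near) term neonates with
    perinatal asphyxia undergoing controlled therapeutic hypothermia,
    with gestational age and a post-rewarming (study day 5) covariate on
    clearance.  Provides analytic multi-infusion concentration prediction
    with piecewise clearance, Monte-Carlo simulation, synthetic cohort
    generation emulating the sparse neonatal sampling design, Laplacian
    conditional-mode (FOCE-I style) maximum-likelihood estimation with
    empirical-Bayes individual estimates, stepwise covariate selection,
    nonparametric bootstrap, and a model-validation battery: prediction
    error metrics (MPE, RMSE) with stratification and bootstrap confidence
    intervals, prediction-corrected visual predictive checks, and
    normalized prediction distribution errors with significance tests.
    Dosing-regimen evaluation by simulation reports peak and trough target
    attainment for gestational-age stratified empiric regimens.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    statmod,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
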