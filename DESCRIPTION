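Package: cagecal
Title: Decomposition and Analysis of Fasting-Refeeding Metabolic Cage Calorimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meal-response indirect calorimetry in small animals.
    Corrects gas-exchange traces for first-order chamber washout, separates
    resting from activity-specific energy expenditure with a state-space
    (Kalman) decomposition, and derives session-level physiology: basal
    metabolic rate, thermic effect of feeding, resting and activity
    respiratory quotients, glucose and lipid oxidation, and metabolic-mass
    normalised rates. Includes body-composition bookkeeping (MRI fat-mass
    trajectories, adiposity gains, carbohydrate/fat sensitivity
    classification), nested linear mixed-effects meal-response models, and a
    seeded synthetic-data generator emulating cohort heterogeneity and cage
    physics so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    nlme,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
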