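Package: cdmst
Title: Automated Assembly of Multistage Tests for Cognitive Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds computerized multistage tests (MST) on top of cognitive
    diagnosis models. Provides the G-DINA response model with simulation of
    item banks, knowledge states and response matrices; a cognitive-diagnosis
    item-difficulty index (mean correct-response probability over all
    knowledge states) with equal-width difficulty binning; tetrachoric
    attribute reliability from marginal mastery probabilities; a normalized
    weighted absolute deviation heuristic (NWADH) that assembles parallel
    three-stage panels under reliability targets and non-statistical
    constraints; evaluation criteria (reliability deviations, constraint
    violations, expected number-correct scores, Cronbach's alpha, Rasch
    cross-validation of the difficulty index); and a replication study
    runner with tidy outputs and ggplot2 figures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    mvtnorm,
    tidyr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
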