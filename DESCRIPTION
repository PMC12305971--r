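Package: strideboard
Title: Reconstructing Expert-Board Stroke Mobility Scores from Instrumented Gait Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reproducing interdisciplinary expert-board Stroke
    Mobility Score (SMS) assessments from instrumented gait analysis.
    Includes a synthetic hemiparetic-cohort generator driven by latent
    per-subscore severities, extraction of the 680-entry stride-pair feature
    vector (spatiotemporal gait parameters, numerical characterizations of
    joint-angle and normalized-angular-velocity curves, walking-aid flags),
    mode-with-tiebreaker aggregation of five-rater panels, patient-grouped
    stratified splitting with bias-correcting stride-pair weights, two-step
    feature selection via expert masks and the Alexander-Govern
    heteroscedastic one-way test, grid-searched decision-tree and multilayer
    perceptron regressors with representative-pair-aware cross-validation,
    patient-level evaluation with ICC(1,1) inter-rater reliability, and
    global model explanation via split-gain and permutation importance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    generics,
    readr,
    jsonlite,
    ggplot2,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
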