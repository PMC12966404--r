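Package: scmsim
Title: Bed-Day Simulation and Adverse-Event Prediction for Chemotherapy-Based Stem Cell Mobilization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the inpatient course of multiple myeloma patients undergoing
    chemotherapy-based stem cell mobilization and collection. Provides a tidy
    per-patient timeline cohort model with CSV/JSON interchange, a deterministic
    fixture cohort reproducing published summary marginals, a parametric
    synthetic cohort generator with plantable covariate effects, a scenario
    simulator that converts admission policies into hospital bed-days with
    bootstrap confidence intervals, and a two-step (occurrence, then onset)
    severe-adverse-event prediction framework with nested cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    pROC,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
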