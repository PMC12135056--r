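Package: pkmlval
Title: Machine-Learning Prediction of Plasma Concentration-Time Profiles
    with Virtual-Population Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to validate machine-learning prediction of drug plasma
    concentration-time profiles against population-pharmacokinetic
    simulation. Generates virtual patient cohorts from a covariate model
    with log-normal inter-individual variability (the published
    remifentanil model is built in), simulates constant-rate infusion
    kinetics with an analytic three-compartment solver, designs
    train/test splits by hierarchical clustering of patient features,
    trains a panel of regression learners (penalised linear models,
    k-nearest neighbours, support vector machines, random forests,
    gradient boosting, neural networks) against a naive per-time-point
    average baseline, and scores predictions with log-scale mean squared
    error and R-squared. A synthetic clinical-cohort generator emulates
    real-world dosing variability so the whole pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    withr,
    jsonlite,
    yaml,
    ranger,
    xgboost,
    glmnet,
    e1071,
    nnet,
    caret
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    readxl
Config/testthat/edition: 3
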