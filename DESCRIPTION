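Package: pstnet
Title: Progressive Self-Transfer Networks for Longitudinal Disease-Onset Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts disease onset from discrete multivariate longitudinal
    panels (participant x time-step x feature) with a progressive self-transfer
    framework: four time-series task-construction schemes (expanding window,
    rolling window, and two skipping-series resolutions) feed sequentially
    trained multilayer recurrent classifiers whose best-epoch weights transfer
    task to task, combined by a soft-voting ensemble and evaluated with
    repeated stratified cross-validation. Includes a bidirectional recurrent
    imputer with temporal decay for missing values, L1-penalized feature
    selection with a missingness prefilter, diagnostic-criteria labeling for
    diabetes onset, and a synthetic biannual cohort generator with calibrated
    rising prevalence for fully reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'cli_config.R'
    'ensemble_eval.R'
    'feature_selection.R'
    'imputation.R'
    'labeling.R'
    'pstnet-package.R'
    'synth_cohort.R'
    'trainer.R'
    'windowing.R'
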