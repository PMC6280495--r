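Package: bjlasso
Title: Lasso-Regularized Buckley-James Regression for Left-Censored Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Linear regression for outcomes that are left-censored at a
    known detection limit (for example log10 HIV viral load below the
    quantification threshold of an assay) with many, possibly more than n,
    predictors. Implements iterative and one-step Lasso-regularized
    Buckley-James least-squares estimators with parametric
    (truncated-Gaussian) and non-parametric (Kaplan-Meier) conditional-mean
    imputation of censored values, censoring-aware stratified K-fold
    cross-validation with both an imputation-based squared loss and a
    Gaussian likelihood loss, simple detection-limit substitution baselines,
    unpenalized Tobit maximum likelihood and censored least-absolute-deviation
    estimators for low-dimensional comparison, and seeded simulation
    generators producing correlated binary mutation predictors with
    calibrated censoring rates for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    survival,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
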