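Package: optivalid
Title: Optimism-Corrected Internal Validation of Logistic Prediction Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying how data-resampling techniques correct the
    optimism of performance measures of logistic regression models in small
    samples. Implements three model estimators (maximum likelihood, Firth's
    penalized likelihood, and ridge regression tuned by a penalized AIC with
    effective degrees of freedom), three performance measures (c-statistic,
    discrimination slope, Brier score), and five optimism-correction
    techniques (pooled leave-one-out cross-validation, leave-pair-out
    cross-validation, repeated 5-fold cross-validation, the enhanced
    bootstrap, and the .632+ bootstrap). A synthetic data-generating
    mechanism with mixed covariate types, a linear-programming separation
    diagnostic, and a simulation driver with independent-validation gold
    standards, mean differences, root mean squared differences, and
    Monte-Carlo standard errors are included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
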