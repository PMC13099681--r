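Package: emirt
Title: Accelerated EM Estimation for Two-Parameter Logistic Item Response Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Marginal maximum-likelihood estimation of unidimensional
    two-parameter logistic (2PL) item response models on large response
    matrices.  Provides the classical full-data Bock-Aitkin EM algorithm and
    a two-stage accelerated variant that switches, once a log-likelihood
    based rule detects the neighbourhood of the maximum, to partial E-steps
    over shuffled disjoint person subsets with damped Newton M-updates and
    Polyak-style iterate averaging.  Standard errors come from an
    incrementally accumulated empirical cross-product (XPD) information
    matrix, with a Fisher expected-information gold standard by full
    response-pattern enumeration for simulation benchmarking.  Includes
    generators for plain 2PL data, grid-sampled item banks, multi-form
    planned-missingness designs, and testlet-2PL misspecification data,
    plus bias/RMSE evaluation metrics and a study-orchestration harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
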