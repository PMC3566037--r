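Package: capload
Title: Capacity-Load Modelling of Childhood Blood Pressure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing a capacity-load model of childhood blood
    pressure in birth cohorts: LMS growth-reference z-scoring with
    invertible centile arithmetic, Hadi forward-search multivariate
    outlier screening, standardised unexplained-residual predictors
    (relative lean and fat mass, conditional growth velocities), the
    linear and logistic regression suites that contrast marginal and
    load-adjusted effects of birth weight and postnatal growth, and a
    structural cohort simulator with planted coefficients and a
    closed-form coefficient oracle for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
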