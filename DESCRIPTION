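Package: ivbalance
Title: Propensity-Score Weighting Under Instrumental Variables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and estimation toolkit for comparing strategies that
    protect augmented inverse-probability-of-treatment weighting (AIPTW)
    against instrumental variables and limited overlap: the outcome-adaptive
    lasso (penalized propensity-score model tuned by outcome associations),
    stable balancing weights (minimum-variance weights under approximate
    mean-balance constraints solved as a quadratic program), and stable
    confounder selection (nested covariate sets screened by an
    inverse-variance-weighted moving average). Includes the data-generating
    process with confounders, outcome-only predictors, instruments and
    spurious covariates, a Monte Carlo harness producing bias, MSE, relative
    MSE, empirical and average standard errors and coverage with Monte Carlo
    uncertainty, and weighting diagnostics (effective sample size, maximum
    weight, population standardized differences).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
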