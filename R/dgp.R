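#' Define a simulation scenario
#'
#' A scenario bundles every knob of the data-generating process: `n` units,
#' `J` equicorrelated standard-normal covariates (common correlation `rho`),
#' a binary treatment from a logistic model with coefficients
#' `(0.5, 0.5, 0, 0, theta, theta, 0, ..., 0)`, and a continuous outcome
#' `Y = tau*Z + X %*% alpha + eps` with `alpha = (1, 1, 1, 1, 0, ..., 0)` and
#' Gaussian noise. `X1`, `X2` are true confounders, `X3`, `X4` predict only
#' the outcome, `X5`, `X6` are instruments of strength `theta`, and the
#' remaining `J - 6` covariates are spurious. Under
#' `effect_type = "heterogeneous"` the treatment term becomes
#' `(1 + X1 + X2) * Z`; either way the average treatment effect is 1.
#'
#' @param n Sample size (at least 2).
#' @param J Number of covariates; at least 6 because the first six covariates
#'   carry fixed structural roles.
#' @param rho Common pairwise correlation of the covariates, in `[0, 1)`.
#' @param theta Instrument strength; the study grids use 0.5 (moderate)
#'   and 1 (strong).
#' @param effect_type `"homogeneous"` or `"heterogeneous"`.
#' @param seed Master seed for the scenario; covariates, treatment draws and
#'   outcome noise use independent sub-streams derived from it so each
#'   component is reproducible in isolation.
#' @param tau True average treatment effect (fixed at 1 in the study design).
#' @param beta0,alpha0 Treatment and outcome intercepts.
#' @param sigma_eps Outcome noise standard deviation (default 2; 0 gives
#'   noise-free data, useful for exact-recovery checks).
#'
#' @return An object of class `scenario_config` (a named list).
#' @seealso [simulate_scenario()]
#' @export
#' @examples
#' cfg <- scenario_config(n = 500, J = 20, rho = 0, theta = 0.5, seed = 1)
#' dat <- simulate_scenario(cfg)
scenario_config <- function(n, J = 20, rho = 0, theta = 0.5,
                            effect_type = c("homogeneous", "heterogeneous"),
                            seed = 1L, tau = 1, beta0 = 0, alpha0 = 0,
                            sigma_eps = 2) {
  effect_type <- match.arg(effect_type)
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    stop("`n` must be a single integer >= 2.", call. = FALSE)
  }
  if (!is.numeric(J) || length(J) != 1L || J < 6) {
    stop("`J` must be at least 6: X1..X6 have fixed structural roles.",
         call. = FALSE)
  }
  check_rho(rho)
  if (sigma_eps < 0) stop("`sigma_eps` must be nonnegative.", call. = FALSE)
  structure(
    list(n = as.integer(n), J = as.integer(J), rho = rho, theta = theta,
         effect_type = effect_type, tau = tau, beta0 = beta0,
         alpha0 = alpha0, sigma_eps = sigma_eps, seed = as.integer(seed)),
    class = "scenario_config"
  )
}

check_rho <- function(rho) {
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1) {
    stop("`rho` must lie in [0, 1): the equicorrelation matrix must be ",
         "positive definite.", call. = FALSE)
  }
  invisible(rho)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  n = %d, J = %d, rho = %g, theta = %g\n", x$n, x$J, x$rho,
              x$theta))
  cat(sprintf("  effect_type = %s, tau = %g, sigma_eps = %g, seed = %d\n",
              x$effect_type, x$tau, x$sigma_eps, x$seed))
  invisible(x)
}

#' Draw equicorrelated standard-normal covariates
#'
#' Rows are i.i.d. draws from a `J`-variate normal with zero means, unit
#' variances and all pairwise correlations equal to `rho`, generated through
#' the one-factor representation `sqrt(rho) * g + sqrt(1 - rho) * e`.
#'
#' @inheritParams scenario_config
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return An `n` by `J` numeric matrix.
#' @export
generate_covariates <- function(n, J, rho, seed = NULL) {
  if (n < 2 || J < 1) stop("need n >= 2 and J >= 1.", call. = FALSE)
  check_rho(rho)
  if (!is.null(seed)) set.seed(seed)
  shared <- rnorm(n)
  noise <- matrix(rnorm(n * J), n, J)
  X <- sqrt(rho) * shared + sqrt(1 - rho) * noise
  colnames(X) <- paste0("X", seq_len(J))
  X
}

#' Treatment-model coefficients of the study design
#'
#' `(0.5, 0.5, 0, 0, theta, theta, 0, ..., 0)`: confounders enter with 0.5,
#' the two instruments with `theta`, everything else with 0.
#'
#' @inheritParams scenario_config
#' @return A length-`J` numeric vector.
#' @export
treatment_coefficients <- function(J, theta) {
  if (J < 6) stop("`J` must be at least 6.", call. = FALSE)
  c(0.5, 0.5, 0, 0, theta, theta, rep(0, J - 6))
}

#' Outcome-model coefficients of the study design
#'
#' `(1, 1, 1, 1, 0, ..., 0)`: confounders and outcome-only predictors enter
#' with 1, instruments and spurious covariates with 0.
#'
#' @inheritParams scenario_config
#' @return A length-`J` numeric vector.
#' @export
outcome_coefficients <- function(J) {
  if (J < 6) stop("`J` must be at least 6.", call. = FALSE)
  c(1, 1, 1, 1, rep(0, J - 4))
}

#' True propensity scores of the logistic treatment model
#'
#' @param X Covariate matrix.
#' @param beta Length-`ncol(X)` coefficient vector.
#' @param beta0 Intercept.
#' @return Propensity scores `plogis(beta0 + X %*% beta)`, strictly in (0, 1).
#' @export
true_propensity <- function(X, beta, beta0 = 0) {
  X <- as.matrix(X)
  if (length(beta) != ncol(X)) {
    stop("`beta` must have one entry per column of `X`.", call. = FALSE)
  }
  drop(plogis(beta0 + X %*% beta))
}

#' Draw treatment assignments
#'
#' Independent Bernoulli draws at the given propensities.
#'
#' @param true_ps Probabilities in (0, 1).
#' @inheritParams generate_covariates
#' @return Integer 0/1 vector.
#' @export
generate_treatment <- function(true_ps, seed = NULL) {
  if (any(true_ps <= 0 | true_ps >= 1)) {
    stop("`true_ps` must be strictly inside (0, 1).", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  rbinom(length(true_ps), 1L, true_ps)
}

#' Draw outcomes under homogeneous or heterogeneous effects
#'
#' Homogeneous: `Y = tau*Z + alpha0 + X %*% alpha + eps`. Heterogeneous:
#' the treatment term is `(1 + X1 + X2) * Z`, whose mean effect is still 1
#' because `E(1 + X1 + X2) = 1`. `eps` is Gaussian with SD `sigma_eps`.
#'
#' @param X Covariate matrix with at least 2 columns.
#' @param Z Binary treatment vector.
#' @param effect_type `"homogeneous"` or `"heterogeneous"`.
#' @inheritParams scenario_config
#' @inheritParams generate_covariates
#' @return Numeric outcome vector.
#' @export
generate_outcome <- function(X, Z, effect_type = c("homogeneous", "heterogeneous"),
                             tau = 1, alpha0 = 0, sigma_eps = 2, seed = NULL) {
  effect_type <- match.arg(effect_type)
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("`X` needs at least two columns.", call. = FALSE)
  if (nrow(X) != length(Z)) stop("row mismatch between `X` and `Z`.",
                                 call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  alpha <- c(1, 1, 1, 1, rep(0, max(0, ncol(X) - 4)))[seq_len(ncol(X))]
  effect <- switch(effect_type,
    homogeneous = tau * Z,
    heterogeneous = (1 + X[, 1] + X[, 2]) * Z
  )
  eps <- if (sigma_eps > 0) rnorm(nrow(X), 0, sigma_eps) else 0
  drop(effect + alpha0 + X %*% alpha + eps)
}

#' Simulate one dataset from a scenario
#'
#' Generates covariates, true propensity scores, treatment and outcome from
#' the scenario's master seed (independent sub-streams for the three random
#' components). The true propensity scores and true ATE travel with the data
#' as attributes; see [true_ps()].
#'
#' @param config A [scenario_config()].
#' @return A tibble with columns `Y`, `Z`, `X1`..`XJ` and attributes
#'   `true_ps`, `true_ate` and `config`.
#' @export
simulate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  sub <- sample.int(.Machine$integer.max, 3L)
  X <- generate_covariates(config$n, config$J, config$rho, seed = sub[1])
  beta <- treatment_coefficients(config$J, config$theta)
  ps <- true_propensity(X, beta, config$beta0)
  Z <- generate_treatment(ps, seed = sub[2])
  Y <- generate_outcome(X, Z, config$effect_type, tau = config$tau,
                        alpha0 = config$alpha0, sigma_eps = config$sigma_eps,
                        seed = sub[3])
  out <- tibble::as_tibble(as.data.frame(X))
  out <- tibble::add_column(out, Y = Y, Z = as.integer(Z), .before = 1)
  attr(out, "true_ps") <- ps
  attr(out, "true_ate") <- config$tau
  attr(out, "config") <- config
  out
}

#' Extract the true propensity scores attached to a simulated dataset
#'
#' @param data A tibble created by [simulate_scenario()].
#' @return Numeric vector of true propensity scores.
#' @export
true_ps <- function(data) {
  ps <- attr(data, "true_ps")
  if (is.null(ps)) {
    stop("`data` carries no true propensity scores; was it created by ",
         "simulate_scenario()?", call. = FALSE)
  }
  ps
}

#' Fraction of propensity scores outside an overlap range
#'
#' Reports the share of scores strictly below `lo` or strictly above `hi`;
#' boundary values count as non-extreme (the range is closed).
#'
#' @param ps Propensity scores in (0, 1).
#' @param lo,hi Overlap bounds, default `[0.1, 0.9]`.
#' @return A proportion in `[0, 1]`.
#' @export
#' @examples
#' extreme_ps_fraction(c(0.05, 0.5, 0.95, 0.9))  # 0.5
extreme_ps_fraction <- function(ps, lo = 0.1, hi = 0.9) {
  if (length(ps) == 0) stop("`ps` is empty.", call. = FALSE)
  if (any(ps <= 0 | ps >= 1)) stop("`ps` must lie in (0, 1).", call. = FALSE)
  if (lo >= hi) stop("`lo` must be smaller than `hi`.", call. = FALSE)
  mean(ps < lo | ps > hi)
}

# --- delimited / config IO ---------------------------------------------------

covariate_columns <- function(data) {
  nm <- grep("^X[0-9]+$", names(data), value = TRUE)
  nm[order(as.integer(sub("^X", "", nm)))]
}

covariate_matrix <- function(data, covariates = NULL) {
  if (is.null(covariates)) covariates <- covariate_columns(data)
  as.matrix(data[covariates])
}

#' Read and write simulated datasets as CSV
#'
#' The on-disk layout is one row per subject with a header row and columns
#' `Y`, `Z`, `X1`..`XJ`; missing values are rejected on read.
#'
#' @param data Dataset tibble (columns `Y`, `Z`, `X1`..`XJ`).
#' @param path File path.
#' @return `write_scenario_csv()` returns `data` invisibly;
#'   `read_scenario_csv()` returns a tibble.
#' @export
write_scenario_csv <- function(data, path) {
  cols <- c("Y", "Z", covariate_columns(data))
  readr::write_csv(data[cols], path)
  invisible(data)
}

#' @rdname write_scenario_csv
#' @export
read_scenario_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("Y", "Z")
  if (!all(need %in% names(data)) || length(covariate_columns(data)) == 0) {
    stop("expected columns Y, Z and X1..XJ in ", path, call. = FALSE)
  }
  if (anyNA(data)) stop("missing values are not allowed in ", path,
                        call. = FALSE)
  if (!all(data$Z %in% c(0, 1))) stop("`Z` must be binary 0/1.", call. = FALSE)
  data
}

#' Serialize a scenario configuration to YAML
#'
#' @param config A [scenario_config()].
#' @param path File path.
#' @return `write_scenario_config()` returns `config` invisibly;
#'   `read_scenario_config()` returns a `scenario_config`.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(config)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(scenario_config, vals)
}
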