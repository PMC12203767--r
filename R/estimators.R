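# Working models and the AIPTW estimator.
#
# The estimator is tau_hat = n^-1 sum_i [ (2Z_i - 1) W_i (Y_i - m_{Z_i,i})
#   + m_{1,i} - m_{0,i} ],
# with W_i = Z_i/e_i + (1 - Z_i)/(1 - e_i) on the IPW scale, and its variance
# estimated from the sample variance of the per-unit influence contributions
# psi_i = (2Z_i - 1) W_i (Y_i - m_{Z_i,i}) + m_{1,i} - m_{0,i} - tau_hat.

PS_CLIP <- 1e-6

#' Fit a maximum-likelihood logistic propensity-score model
#'
#' IRLS via `stats::glm.fit` (tolerance 1e-8, up to 100 iterations). Fitted
#' probabilities are clipped to `[1e-6, 1 - 1e-6]` before any inversion so
#' separation cannot produce infinite weights; separation or non-convergence
#' is flagged with a warning rather than an error.
#'
#' @param X Covariate matrix (may have zero columns for an intercept-only fit).
#' @param Z Binary treatment vector with both classes present.
#' @return A list of class `ps_fit`: `intercept`, `coef`, `fitted_ps`,
#'   `adjustment_set`, `converged`, `separation`.
#' @export
fit_logistic_ps <- function(X, Z) {
  X <- as.matrix(X)
  if (length(unique(Z)) < 2) {
    stop("`Z` is constant: cannot fit a propensity model.", call. = FALSE)
  }
  design <- cbind(`(Intercept)` = 1, X)
  flags <- character(0)
  fit <- withCallingHandlers(
    stats::glm.fit(design, Z, family = binomial(),
                   control = glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  separation <- any(grepl("numerically 0 or 1", flags))
  if (separation || !fit$converged) {
    warning("propensity model did not converge cleanly (possible separation); ",
            "fitted probabilities were clipped.", call. = FALSE)
  }
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  structure(
    list(intercept = unname(cf[1]), coef = cf[-1],
         fitted_ps = clip_ps(fit$fitted.values),
         adjustment_set = colnames(X),
         converged = fit$converged, separation = separation),
    class = "ps_fit"
  )
}

clip_ps <- function(ps) pmin(pmax(ps, PS_CLIP), 1 - PS_CLIP)

#' Fit the shared outcome model by ordinary least squares
#'
#' One joint main-effects regression of `Y` on an intercept, `Z` and the
#' covariates; `m1`/`m0` are the fitted values with `Z` set to 1/0, so their
#' difference equals the `Z` coefficient for every unit. Aliased columns are
#' dropped with a warning.
#'
#' @param X Covariate matrix.
#' @param Z Binary treatment vector.
#' @param Y Outcome vector.
#' @return A list: `m1`, `m0`, `coef` (named, including `(Intercept)` and `Z`).
#' @export
fit_outcome_model <- function(X, Z, Y) {
  X <- as.matrix(X)
  n <- length(Y)
  if (nrow(X) != n || length(Z) != n) stop("length mismatch.", call. = FALSE)
  design <- cbind(`(Intercept)` = 1, Z = Z, X)
  fit <- stats::lm.fit(design, Y)
  cf <- fit$coefficients
  if (anyNA(cf)) {
    warning("rank-deficient outcome model: dropping aliased columns ",
            paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
    cf[is.na(cf)] <- 0
  }
  base <- drop(design %*% cf)
  tau_z <- unname(cf["Z"])
  list(m1 = base + (1 - Z) * tau_z, m0 = base - Z * tau_z, coef = cf)
}

#' Inverse-probability-of-treatment weights
#'
#' Treated units receive `1/e`, controls `1/(1 - e)`; the result is on the
#' IPW scale expected by [aiptw()].
#'
#' @param fitted_ps Estimated propensity scores in (0, 1).
#' @param Z Binary treatment vector.
#' @param source Label recording where the propensities came from.
#' @return A list of class `weight_vector` with `weights`, `scale = "ipw"`,
#'   and `source`.
#' @export
ipw_weights <- function(fitted_ps, Z, source = "logistic_ps") {
  if (any(fitted_ps <= 0 | fitted_ps >= 1)) {
    stop("`fitted_ps` must be strictly inside (0, 1).", call. = FALSE)
  }
  w <- ifelse(Z == 1, 1 / fitted_ps, 1 / (1 - fitted_ps))
  new_weight_vector(w, scale = "ipw", source = source)
}

new_weight_vector <- function(weights, scale = c("ipw", "hajek_group"),
                              source = "logistic_ps") {
  scale <- match.arg(scale)
  if (any(weights < 0)) stop("weights must be nonnegative.", call. = FALSE)
  structure(list(weights = weights, scale = scale, source = source),
            class = "weight_vector")
}

resolve_ipw_weights <- function(weights) {
  if (inherits(weights, "weight_vector")) {
    if (weights$scale != "ipw") {
      stop("weights are on the within-group (Hajek) scale; rescale to the ",
           "IPW scale (multiply by n) before computing AIPTW.", call. = FALSE)
    }
    weights$weights
  } else {
    as.numeric(weights)
  }
}

#' AIPTW point estimate
#'
#' @param Y Outcome vector.
#' @param Z Binary treatment vector.
#' @param weights IPW-scale weights (numeric or a `weight_vector`); weights on
#'   the within-group scale are rejected.
#' @param m1,m0 Outcome-model predictions at `Z = 1` and `Z = 0`.
#' @return The doubly robust ATE estimate.
#' @export
aiptw <- function(Y, Z, weights, m1, m0) {
  w <- resolve_ipw_weights(weights)
  m_obs <- ifelse(Z == 1, m1, m0)
  mean((2 * Z - 1) * w * (Y - m_obs) + m1 - m0)
}

#' Influence-function standard error of the AIPTW estimate
#'
#' Sample standard deviation (n - 1 divisor) of the per-unit influence
#' contributions, divided by `sqrt(n)`.
#'
#' @inheritParams aiptw
#' @param tau_hat The AIPTW point estimate.
#' @return Standard error (nonnegative scalar).
#' @export
influence_se <- function(Y, Z, weights, m1, m0, tau_hat) {
  if (length(Y) < 2) stop("need at least 2 units for a standard error.",
                          call. = FALSE)
  w <- resolve_ipw_weights(weights)
  m_obs <- ifelse(Z == 1, m1, m0)
  psi <- (2 * Z - 1) * w * (Y - m_obs) + m1 - m0 - tau_hat
  sd(psi) / sqrt(length(Y))
}

#' Wald confidence interval
#'
#' @param tau_hat Point estimate.
#' @param se Standard error.
#' @param level Coverage level in (0, 1).
#' @return Named vector `c(ci_low, ci_high)`.
#' @export
wald_ci <- function(tau_hat, se, level = 0.95) {
  if (se < 0) stop("`se` must be nonnegative.", call. = FALSE)
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1).",
                                     call. = FALSE)
  z <- qnorm(1 - (1 - level) / 2)
  c(ci_low = tau_hat - z * se, ci_high = tau_hat + z * se)
}

new_effect_fit <- function(tau_hat, se, method, adjustment_set, extra = list(),
                           class = "aiptw_fit", level = 0.95) {
  ci <- wald_ci(tau_hat, se, level)
  structure(
    c(list(tau_hat = tau_hat, se = se, ci_low = unname(ci[1]),
           ci_high = unname(ci[2]), method = method,
           adjustment_set = adjustment_set, level = level), extra),
    class = unique(c(class, "aiptw_fit"))
  )
}

#' Doubly robust ATE estimation on a fixed adjustment set
#'
#' Fits the logistic propensity-score model and the shared OLS outcome model
#' on the requested covariates, then returns the AIPTW estimate with its
#' influence-function standard error and Wald interval. This is the "plain"
#' estimator used for the Target / Confounders / All-covariates variants; the
#' data-adaptive alternatives are [estimate_oal()], [estimate_sbw()] and
#' [estimate_scs()].
#'
#' @param data A data frame with columns `Y`, `Z` and covariates `X1`..`XJ`.
#' @param covariates Character vector of covariate columns to adjust for;
#'   default all `X` columns.
#' @param method Label stored with the result.
#' @return An object of class `aiptw_fit`; see [glance.aiptw_fit()] and
#'   [tidy.aiptw_fit()].
#' @export
#' @examples
#' dat <- simulate_scenario(scenario_config(500, J = 20, seed = 3))
#' fit <- estimate_aiptw(dat, covariates = paste0("X", 1:4), method = "Target")
#' glance(fit)
estimate_aiptw <- function(data, covariates = NULL, method = "AIPTW") {
  covariates <- covariates %||% covariate_columns(data)
  X <- covariate_matrix(data, covariates)
  Z <- data$Z
  Y <- data$Y
  ps <- fit_logistic_ps(X, Z)
  om <- fit_outcome_model(X, Z, Y)
  w <- ipw_weights(ps$fitted_ps, Z)
  tau <- aiptw(Y, Z, w, om$m1, om$m0)
  se <- influence_se(Y, Z, w, om$m1, om$m0, tau)
  new_effect_fit(tau, se, method, covariates,
                 extra = list(ps_fit = ps, outcome_coef = om$coef,
                              weights = w))
}

#' @export
print.aiptw_fit <- function(x, ...) {
  cat(sprintf("<%s> method: %s\n", class(x)[1], x$method))
  cat(sprintf("  ATE %.4f (SE %.4f), %g%% CI [%.4f, %.4f]\n",
              x$tau_hat, x$se, 100 * x$level, x$ci_low, x$ci_high))
  cat(sprintf("  adjustment set (%d): %s\n", length(x$adjustment_set),
              paste(utils::head(x$adjustment_set, 8), collapse = ", ")))
  invisible(x)
}

#' Glance at a fitted effect estimate
#'
#' One row per fit with the point estimate, influence-function standard
#' error, Wald interval and the size of the adjustment set.
#'
#' @param x An `aiptw_fit` (also `oal_fit`, `sbw_fit`, `scs_fit`).
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.aiptw_fit <- function(x, ...) {
  tibble::tibble(method = x$method, estimate = x$tau_hat, se = x$se,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 n_covariates = length(x$adjustment_set))
}

#' Tidy a plain AIPTW fit
#'
#' Term-level view of the two working models: propensity-score and outcome
#' coefficients, one row per (model, term).
#'
#' @param x An `aiptw_fit`.
#' @param ... Unused.
#' @return A tibble with columns `model`, `term`, `estimate`.
#' @export
tidy.aiptw_fit <- function(x, ...) {
  ps <- tibble::tibble(model = "propensity",
                       term = c("(Intercept)", names(x$ps_fit$coef)),
                       estimate = c(x$ps_fit$intercept,
                                    unname(x$ps_fit$coef)))
  om <- tibble::tibble(model = "outcome", term = names(x$outcome_coef),
                       estimate = unname(x$outcome_coef))
  dplyr::bind_rows(ps, om)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
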