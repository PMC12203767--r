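# Outcome-adaptive lasso for the propensity-score model.
#
# The PS coefficients maximize the penalized log-likelihood (sum scale)
#   sum_i [ Z_i (b0 + x_i'b) - log(1 + exp(b0 + x_i'b)) ] - lambda * sum_j w_j |b_j|
# with penalty weights w_j = |alpha_tilde_j|^(-gamma) taken from the outcome
# model, so covariates with weak outcome associations (instruments, spurious
# covariates) are shrunk hardest. For each lambda = n^exponent the exponent
# gamma solves lambda * n^(gamma/2 - 1) = n^2; the lambda minimizing the
# weighted absolute mean difference (wAMD) of covariates is kept.

#' Tuning parameters for the outcome-adaptive lasso
#'
#' @param lambda_exponents Exponents `a` of the candidate penalties
#'   `lambda = n^a`.
#' @param gamma_target_exponent Right-hand-side exponent `t` of the calibration
#'   `lambda * n^(gamma/2 - 1) = n^t`; the default 2 gives
#'   `gamma = 2 * (1 + t - log_n lambda)`.
#' @param omega_cap Cap on the penalty weights so a zero outcome coefficient
#'   yields a finite (but effectively excluding) penalty.
#' @return A list of class `oal_control`.
#' @export
oal_control <- function(lambda_exponents = c(-10, -5, -2, -1, -0.75, -0.5,
                                             -0.25, 0.25, 0.49),
                        gamma_target_exponent = 2, omega_cap = 1e8) {
  stopifnot(omega_cap > 0, length(lambda_exponents) >= 1)
  structure(list(lambda_exponents = lambda_exponents,
                 gamma_target_exponent = gamma_target_exponent,
                 omega_cap = omega_cap),
            class = "oal_control")
}

#' Standardize covariate columns
#'
#' Centers to mean zero and scales to unit standard deviation, keeping the
#' transform so estimates can be mapped back; the adaptive penalty is only
#' meaningful on a common scale.
#'
#' @param X Covariate matrix.
#' @return A list: `X_std`, `means`, `sds`.
#' @export
standardize <- function(X) {
  X <- as.matrix(X)
  sds <- apply(X, 2, sd)
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad)) {
    stop("constant column(s): ", paste(colnames(X)[bad], collapse = ", "),
         call. = FALSE)
  }
  means <- colMeans(X)
  list(X_std = scale(X, center = means, scale = sds)[, , drop = FALSE],
       means = means, sds = sds)
}

#' Outcome-association coefficients on standardized covariates
#'
#' OLS of `Y` on an intercept, `Z` and all standardized covariates; returns
#' the covariate coefficients only. These drive the adaptive penalty.
#'
#' @param X_std Standardized covariate matrix.
#' @param Z,Y Treatment and outcome vectors.
#' @return Named numeric vector `alpha_tilde`.
#' @export
outcome_association_coefs <- function(X_std, Z, Y) {
  fit <- stats::lm.fit(cbind(1, Z = Z, X_std), Y)
  cf <- fit$coefficients
  if (anyNA(cf)) stop("rank-deficient design in the outcome model.",
                      call. = FALSE)
  cf[-(1:2)]
}

#' Solve the penalty exponent gamma for a given lambda
#'
#' `gamma = 2 * (1 + t - log_n(lambda))` satisfies
#' `lambda * n^(gamma/2 - 1) = n^t` exactly.
#'
#' @param lambda Positive penalty value.
#' @param n Sample size (> 1).
#' @param target_exponent The exponent `t` (default 2).
#' @return The exponent `gamma`.
#' @export
#' @examples
#' gamma_for_lambda(500^-2, 500)  # 10
gamma_for_lambda <- function(lambda, n, target_exponent = 2) {
  if (n <= 1) stop("`n` must exceed 1.", call. = FALSE)
  if (lambda <= 0) stop("`lambda` must be positive.", call. = FALSE)
  2 * (1 + target_exponent - log(lambda) / log(n))
}

#' Adaptive penalty weights from outcome associations
#'
#' `omega_j = min(|alpha_tilde_j|^(-gamma), omega_cap)`; a zero coefficient
#' maps to the cap.
#'
#' @param alpha_tilde Outcome-model covariate coefficients.
#' @param gamma Penalty exponent (> 1).
#' @param omega_cap Cap on the weights.
#' @return Numeric vector of penalty weights.
#' @export
penalty_weights <- function(alpha_tilde, gamma, omega_cap = 1e8) {
  if (gamma <= 1) stop("`gamma` must exceed 1.", call. = FALSE)
  pmin(abs(alpha_tilde)^(-gamma), omega_cap)
}

#' Weighted-L1 penalized logistic propensity model
#'
#' Maximizes the sum-scale penalized log-likelihood with an unpenalized
#' intercept. Internally delegates to [glmnet::glmnet()], which minimizes the
#' mean negative log-likelihood plus `lambda_glmnet * sum(pf_j |b_j|)` with
#' penalty factors rescaled to sum to the number of covariates; the exact
#' mapping is `pf = omega`, `lambda_glmnet = (lambda / n) * sum(omega) / J`.
#'
#' @param X_std Standardized covariate matrix.
#' @param Z Binary treatment vector.
#' @param lambda Penalty on the sum-log-likelihood scale.
#' @param omega Per-covariate penalty weights.
#' @return Named vector: `(Intercept)` followed by the covariate coefficients.
#' @export
fit_penalized_logistic <- function(X_std, Z, lambda, omega) {
  X_std <- as.matrix(X_std)
  n <- nrow(X_std)
  J <- ncol(X_std)
  stopifnot(lambda >= 0, all(omega >= 0), length(omega) == J)
  if (lambda == 0) {
    fit <- fit_logistic_ps(X_std, Z)
    return(c(`(Intercept)` = fit$intercept, fit$coef))
  }
  lam_g <- (lambda / n) * sum(omega) / J
  # a short descending path ending at the target improves glmnet's warm starts
  path <- exp(seq(log(lam_g * 100), log(lam_g), length.out = 20))
  fit <- glmnet::glmnet(X_std, Z, family = "binomial", alpha = 1,
                        standardize = FALSE, penalty.factor = omega,
                        lambda = path, thresh = 1e-12, maxit = 1e6)
  cf <- suppressWarnings(
    as.numeric(coef(fit, s = lam_g, exact = TRUE, x = X_std, y = Z,
                    penalty.factor = omega))
  )
  if (anyNA(cf)) stop("penalized logistic fit failed to converge.",
                      call. = FALSE)
  names(cf) <- c("(Intercept)", colnames(X_std))
  cf
}

#' Weighted absolute mean difference of covariates
#'
#' Imbalance between Hajek-weighted treated and control covariate means,
#' weighted by the magnitude of each covariate's outcome association:
#' covariates irrelevant to the outcome contribute nothing, so shrinking
#' instruments away is not penalized.
#'
#' @param X Covariate matrix (same scale as `alpha_tilde` was estimated on).
#' @param Z Binary treatment vector.
#' @param fitted_ps Estimated propensity scores in (0, 1).
#' @param alpha_tilde Outcome-association coefficients.
#' @return A nonnegative scalar.
#' @export
wamd <- function(X, Z, fitted_ps, alpha_tilde) {
  X <- as.matrix(X)
  if (any(fitted_ps <= 0 | fitted_ps >= 1)) {
    stop("`fitted_ps` must be strictly inside (0, 1).", call. = FALSE)
  }
  wt <- Z / fitted_ps
  wc <- (1 - Z) / (1 - fitted_ps)
  if (sum(wt) == 0 || sum(wc) == 0) {
    stop("a treatment group carries zero total weight.", call. = FALSE)
  }
  mean_t <- drop(crossprod(X, wt)) / sum(wt)
  mean_c <- drop(crossprod(X, wc)) / sum(wc)
  sum(abs(alpha_tilde) * abs(mean_t - mean_c))
}

#' Outcome-adaptive lasso AIPTW estimate
#'
#' Standardizes the covariates, estimates the outcome associations once,
#' traces the lambda grid (each lambda with its calibrated gamma and penalty
#' weights), picks the lambda minimizing the wAMD (ties broken toward the
#' smaller lambda, i.e. less shrinkage), and feeds the penalized propensity
#' scores into the AIPTW estimator. The outcome model for the final estimate
#' uses the covariates with nonzero penalized coefficients, sharing the
#' adjustment set with the PS model.
#'
#' @param data A data frame with columns `Y`, `Z`, `X1`..`XJ`.
#' @param control An [oal_control()].
#' @return An object of class `oal_fit` (also `aiptw_fit`): the usual effect
#'   fields plus `alpha_tilde`, `path` (per-lambda tibble), `selected_lambda`,
#'   `selected_exponent`, `selected_set`, `fitted_ps`, `coef_std`.
#' @export
#' @examples
#' dat <- simulate_scenario(scenario_config(400, J = 20, theta = 1, seed = 7))
#' fit <- estimate_oal(dat)
#' glance(fit)
#' tidy(fit)  # the lambda path
estimate_oal <- function(data, control = oal_control()) {
  X <- covariate_matrix(data)
  Z <- data$Z
  Y <- data$Y
  n <- nrow(X)
  std <- standardize(X)
  alpha_tilde <- outcome_association_coefs(std$X_std, Z, Y)

  grid <- tibble::tibble(lambda_exponent = sort(control$lambda_exponents))
  path <- purrr::pmap_dfr(grid, function(lambda_exponent) {
    lambda <- n^lambda_exponent
    gamma <- gamma_for_lambda(lambda, n, control$gamma_target_exponent)
    omega <- penalty_weights(alpha_tilde, gamma, control$omega_cap)
    cf <- fit_penalized_logistic(std$X_std, Z, lambda, omega)
    ps <- clip_ps(drop(plogis(cf[1] + std$X_std %*% cf[-1])))
    tibble::tibble(
      lambda_exponent = lambda_exponent, lambda = lambda, gamma = gamma,
      wamd = wamd(std$X_std, Z, ps, alpha_tilde),
      n_nonzero = sum(cf[-1] != 0),
      coef = list(cf), fitted_ps = list(ps)
    )
  })

  # ties (within floating-point noise) break toward the smaller lambda
  best <- which(path$wamd <= min(path$wamd) + 1e-10)[1]
  cf <- path$coef[[best]]
  ps <- path$fitted_ps[[best]]
  selected <- names(cf[-1])[cf[-1] != 0]

  om <- fit_outcome_model(covariate_matrix(data, selected), Z, Y)
  w <- ipw_weights(ps, Z, source = "oal_ps")
  tau <- aiptw(Y, Z, w, om$m1, om$m0)
  se <- influence_se(Y, Z, w, om$m1, om$m0, tau)
  new_effect_fit(
    tau, se, "OAL", selected, class = "oal_fit",
    extra = list(alpha_tilde = alpha_tilde,
                 path = path[c("lambda_exponent", "lambda", "gamma", "wamd",
                               "n_nonzero", "coef")],
                 selected_lambda = path$lambda[best],
                 selected_exponent = path$lambda_exponent[best],
                 selected_set = selected, fitted_ps = ps,
                 coef_std = cf, weights = w, outcome_coef = om$coef)
  )
}

#' Tidy the outcome-adaptive-lasso path
#'
#' One row per candidate lambda with its exponent, calibrated gamma, wAMD,
#' number of active covariates, and the standardized coefficients spread into
#' columns — the layout used to export the path as CSV.
#'
#' @param x An `oal_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.oal_fit <- function(x, ...) {
  coefs <- purrr::map_dfr(x$path$coef, ~ tibble::as_tibble(as.list(.x)))
  dplyr::bind_cols(
    x$path[c("lambda_exponent", "lambda", "gamma", "wamd", "n_nonzero")],
    coefs
  )
}
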