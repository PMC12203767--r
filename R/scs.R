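# Stable confounder selection.
#
# Covariates are ranked by the weaker of their two association strengths
# (|z| in the full logistic treatment model, |t| in the full OLS outcome
# model), so only covariates related to both treatment and outcome rank
# high. AIPTW is computed along the nested top-k sets; the stability screen
# compares each estimate with an inverse-variance-weighted moving average of
# its window, and the smallest k whose estimate sits closest to its window
# average is selected. The reported standard error is the naive
# influence-function one at the selected k — no post-selection correction —
# which is why coverage can fall below nominal in hard scenarios.

#' Rank covariates by their joint association with treatment and outcome
#'
#' Importance is `min(|z|, |t|)` from the full models; ties are broken by the
#' larger of the two statistics, then by column order.
#'
#' @param X Covariate matrix.
#' @param Z,Y Treatment and outcome vectors.
#' @return A tibble with one row per covariate, ordered by decreasing
#'   importance: `rank`, `covariate`, `index`, `z_stat`, `t_stat`,
#'   `importance`.
#' @export
rank_covariates <- function(X, Z, Y) {
  X <- as.matrix(X)
  ps <- summary(glm(Z ~ X, family = binomial()))$coefficients
  om <- summary(lm(Y ~ Z + X))$coefficients
  z_stat <- abs(ps[-1, "z value"])
  t_stat <- abs(om[-(1:2), "t value"])
  imp <- pmin(z_stat, t_stat)
  ord <- order(-imp, -pmax(z_stat, t_stat), seq_len(ncol(X)))
  tibble::tibble(rank = seq_len(ncol(X)),
                 covariate = colnames(X)[ord], index = ord,
                 z_stat = unname(z_stat[ord]), t_stat = unname(t_stat[ord]),
                 importance = unname(imp[ord]))
}

#' AIPTW estimates along nested covariate sets
#'
#' For each `k`, propensity-score and outcome models share the top-`k`
#' covariates of the ranking. A failed fit is recorded as missing rather
#' than aborting the path.
#'
#' @param X Covariate matrix.
#' @param Z,Y Treatment and outcome vectors.
#' @param ranking Integer vector: covariate indices in priority order.
#' @return A tibble with columns `k`, `tau_hat`, `se`.
#' @export
nested_estimates <- function(X, Z, Y, ranking) {
  X <- as.matrix(X)
  purrr::map_dfr(seq_along(ranking), function(k) {
    res <- tryCatch({
      Xk <- X[, ranking[seq_len(k)], drop = FALSE]
      ps <- suppressWarnings(fit_logistic_ps(Xk, Z))
      om <- fit_outcome_model(Xk, Z, Y)
      w <- ipw_weights(ps$fitted_ps, Z)
      tau <- aiptw(Y, Z, w, om$m1, om$m0)
      c(tau, influence_se(Y, Z, w, om$m1, om$m0, tau))
    }, error = function(e) c(NA_real_, NA_real_))
    tibble::tibble(k = k, tau_hat = res[1], se = res[2])
  })
}

#' Inverse-variance-weighted moving average of nested estimates
#'
#' `MA_k` averages the estimates in the window `k .. k + width - 1` with
#' weights `1/se^2`. A zero standard error gets its weight capped at `1e12`
#' (so it dominates the window); missing entries are dropped from the window;
#' an all-missing window yields `NA`.
#'
#' @param estimates,ses Numeric vectors of the nested estimates and their
#'   standard errors.
#' @param width Window width (default 5).
#' @return Numeric vector of length `length(estimates) - width + 1`.
#' @export
#' @examples
#' ivw_moving_average(1:6, c(1, 1, 2, 2, 1, 1), width = 5)
ivw_moving_average <- function(estimates, ses, width = 5) {
  stopifnot(width >= 1)
  J <- length(estimates)
  if (J < width) stop("need at least `width` estimates.", call. = FALSE)
  vapply(seq_len(J - width + 1), function(k) {
    idx <- k:(k + width - 1)
    est <- estimates[idx]
    w <- pmin(1 / ses[idx]^2, 1e12)
    ok <- is.finite(est) & is.finite(w)
    if (!any(ok)) return(NA_real_)
    sum(est[ok] * w[ok]) / sum(w[ok])
  }, numeric(1))
}

#' Select the smallest stable nested set
#'
#' The chosen `k` minimizes `|tau_hat_k - MA_k|` over the indices where the
#' moving average is defined, with ties broken toward the smallest set. The
#' selected estimate is one of the nested estimates exactly — the moving
#' average is only a screen, never a smoother of the reported value.
#'
#' @inheritParams ivw_moving_average
#' @param moving_average Output of [ivw_moving_average()].
#' @return The selected `k`.
#' @export
select_stable <- function(estimates, ses, moving_average) {
  dev <- abs(estimates[seq_along(moving_average)] - moving_average)
  if (all(!is.finite(dev))) stop("no defined moving-average window.",
                                 call. = FALSE)
  which.min(dev)
}

#' Stable-confounder-selection AIPTW estimate
#'
#' Runs the full ranking, nested-estimate and stability pipeline and returns
#' the estimate at the selected covariate set.
#'
#' @param data A data frame with columns `Y`, `Z`, `X1`..`XJ`.
#' @param width Moving-average window width (default 5).
#' @return An object of class `scs_fit` (also `aiptw_fit`): the usual effect
#'   fields plus `ranking` (tibble), `path` (tibble of `k`, `tau_hat`, `se`,
#'   `moving_average`, `deviation`, `selected`), `selected_k`.
#' @export
#' @examples
#' dat <- simulate_scenario(scenario_config(400, J = 20, theta = 1, seed = 5))
#' fit <- estimate_scs(dat)
#' glance(fit)
estimate_scs <- function(data, width = 5) {
  X <- covariate_matrix(data)
  Z <- data$Z
  Y <- data$Y
  ranking <- rank_covariates(X, Z, Y)
  path <- nested_estimates(X, Z, Y, ranking$index)
  ma <- ivw_moving_average(path$tau_hat, path$se, width)
  k_sel <- select_stable(path$tau_hat, path$se, ma)
  path$moving_average <- c(ma, rep(NA_real_, nrow(path) - length(ma)))
  path$deviation <- abs(path$tau_hat - path$moving_average)
  path$selected <- path$k == k_sel

  new_effect_fit(
    path$tau_hat[k_sel], path$se[k_sel], "SCS",
    ranking$covariate[seq_len(k_sel)], class = "scs_fit",
    extra = list(ranking = ranking, path = path, selected_k = k_sel,
                 window = width)
  )
}

#' Tidy a stable-confounder-selection fit
#'
#' The nested path joined with the ranking: one row per set size `k`.
#'
#' @param x An `scs_fit`.
#' @param ... Unused.
#' @return A tibble with columns `rank`, `covariate`, `importance`,
#'   `tau_hat`, `se`, `moving_average`, `deviation`, `selected`.
#' @export
tidy.scs_fit <- function(x, ...) {
  dplyr::bind_cols(
    x$ranking[c("rank", "covariate", "importance")],
    x$path[c("tau_hat", "se", "moving_average", "deviation", "selected")]
  )
}
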