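# Weighting diagnostics: effective sample size, maximum normalized weight,
# and population standardized differences.

#' Effective sample size of a weighted group
#'
#' `(sum w)^2 / sum(w^2)`: the number of equally weighted observations
#' carrying the same precision. Equal weights give the group size; a single
#' dominating weight drives it toward 1. Invariant to rescaling the weights.
#'
#' @param weights Nonnegative weights of the units in one group.
#' @return A scalar in `[1, length(weights)]`.
#' @export
#' @examples
#' ess(rep(1, 298))   # 298
#' ess(c(1, 1, 2))    # 16/6
ess <- function(weights) {
  check_group_weights(weights)
  sum(weights)^2 / sum(weights^2)
}

#' Maximum normalized weight, in percent
#'
#' `100 * max(w) / sum(w)`; with uniform weights this is `100 / n_group`.
#'
#' @inheritParams ess
#' @return A scalar in `(0, 100]`.
#' @export
max_weight_pct <- function(weights) {
  check_group_weights(weights)
  100 * max(weights) / sum(weights)
}

check_group_weights <- function(weights) {
  if (length(weights) == 0) stop("empty group.", call. = FALSE)
  if (any(weights < 0)) stop("weights must be nonnegative.", call. = FALSE)
  if (sum(weights) == 0) stop("weights sum to zero.", call. = FALSE)
  invisible(weights)
}

#' Population standardized differences of weighted group means
#'
#' For each covariate, the absolute difference between the weighted mean in
#' the group and the unweighted overall mean, divided by the unweighted
#' within-group SD. Shift-invariant, and scale cancels. Values below 0.1 are
#' conventionally read as adequate balance.
#'
#' @param X Covariate matrix or data frame (full sample).
#' @param weights Nonnegative weights for the full sample (any scale).
#' @param Z Binary group indicator for the full sample.
#' @param group Which group (0 or 1) to evaluate.
#' @return A tibble with columns `covariate`, `psd`.
#' @export
psd <- function(X, weights, Z, group) {
  X <- as.matrix(X)
  sel <- Z == group
  if (!any(sel)) stop("group ", group, " is empty.", call. = FALSE)
  w <- weights[sel]
  check_group_weights(w)
  sds <- apply(X[sel, , drop = FALSE], 2, sd)
  bad <- which(sds == 0)
  if (length(bad)) {
    stop("zero within-group SD for ", paste(colnames(X)[bad], collapse = ", "),
         call. = FALSE)
  }
  gm <- drop(crossprod(X[sel, , drop = FALSE], w)) / sum(w)
  tibble::tibble(covariate = colnames(X) %||% paste0("V", seq_len(ncol(X))),
                 psd = unname(abs(gm - colMeans(X)) / sds))
}

#' Weighting diagnostics report
#'
#' Per-group effective sample size and maximum normalized weight, the
#' population standardized differences of every covariate in both groups,
#' and (when true or estimated propensity scores are supplied) the fraction
#' outside the overlap range.
#'
#' @param data A data frame with columns `Z` and `X1`..`XJ`.
#' @param weights Per-unit weights (numeric or a `weight_vector`).
#' @param ps Optional propensity scores for [extreme_ps_fraction()].
#' @return An object of class `diagnostics_report`: a list with tibbles
#'   `groups` (`group`, `n`, `ess`, `max_weight_pct`) and `psd` (`group`,
#'   `covariate`, `psd`), plus `extreme_ps_fraction` (scalar or `NA`).
#' @export
#' @examples
#' dat <- simulate_scenario(scenario_config(300, J = 20, seed = 2))
#' fit <- estimate_aiptw(dat, paste0("X", 1:4))
#' weighting_diagnostics(dat, fit$weights, ps = true_ps(dat))
weighting_diagnostics <- function(data, weights, ps = NULL) {
  X <- covariate_matrix(data)
  Z <- data$Z
  w <- if (inherits(weights, "weight_vector")) weights$weights else
    as.numeric(weights)
  groups <- purrr::map_dfr(c(0L, 1L), function(z) {
    wz <- w[Z == z]
    tibble::tibble(group = z, n = length(wz), ess = ess(wz),
                   max_weight_pct = max_weight_pct(wz))
  })
  psd_tab <- purrr::map_dfr(c(0L, 1L), function(z) {
    tibble::add_column(psd(X, w, Z, z), group = z, .before = 1)
  })
  structure(
    list(groups = groups, psd = psd_tab,
         extreme_ps_fraction = if (is.null(ps)) NA_real_ else
           extreme_ps_fraction(ps)),
    class = "diagnostics_report"
  )
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("<diagnostics_report>\n")
  print(x$groups)
  cat(sprintf("  max |PSD|: %.3f (threshold 0.1)\n", max(x$psd$psd)))
  if (!is.na(x$extreme_ps_fraction)) {
    cat(sprintf("  propensity scores outside [0.1, 0.9]: %.3f\n",
                x$extreme_ps_fraction))
  }
  invisible(x)
}

#' Tidy a diagnostics report
#'
#' @param x A `diagnostics_report`.
#' @param ... Unused.
#' @return The long PSD tibble (`group`, `covariate`, `psd`).
#' @export
tidy.diagnostics_report <- function(x, ...) x$psd

#' @rdname tidy.diagnostics_report
#' @export
glance.diagnostics_report <- function(x, ...) {
  tidyr::pivot_wider(x$groups, names_from = "group",
                     values_from = c("n", "ess", "max_weight_pct")) |>
    tibble::add_column(extreme_ps_fraction = x$extreme_ps_fraction)
}
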