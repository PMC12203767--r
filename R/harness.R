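# Monte Carlo harness: run the six estimator variants over replicated
# scenarios and summarize bias, MSE, relative MSE, empirical and average
# standard errors and coverage, each with a Monte Carlo standard error.

method_labels <- c("Target", "Confounders", "AllCovariates", "OAL", "SCS",
                   "SBW")

#' Covariate sets of the fixed estimator variants
#'
#' `Target` adjusts for the true confounders and outcome predictors
#' (`X1`..`X4`), `Confounders` additionally for the instruments (`X1`..`X6`),
#' `AllCovariates` for everything.
#'
#' @param method One of `"Target"`, `"Confounders"`, `"AllCovariates"`.
#' @param J Number of covariates.
#' @return Character vector of covariate names.
#' @export
adjustment_rule <- function(method, J) {
  switch(method,
    Target = paste0("X", 1:4),
    Confounders = paste0("X", 1:6),
    AllCovariates = paste0("X", seq_len(J)),
    stop("no fixed adjustment rule for method ", method, call. = FALSE)
  )
}

#' Run all requested estimators on one simulated replicate
#'
#' Generates one dataset from `config` (optionally overriding its seed) and
#' applies each requested method; a failing method is recorded with its
#' error message instead of aborting the replicate.
#'
#' @param config A [scenario_config()].
#' @param methods Subset of `c("Target", "Confounders", "AllCovariates",
#'   "OAL", "SCS", "SBW")`.
#' @param seed Optional replicate seed overriding `config$seed`.
#' @param sbw_control,oal_control Tuning objects passed through to
#'   [estimate_sbw()] and [estimate_oal()].
#' @param scs_width Window width for [estimate_scs()].
#' @return A tibble with one row per method: `method`, `estimate`, `se`,
#'   `ci_low`, `ci_high`, `n_covariates`, `error`.
#' @export
run_replicate <- function(config, methods = method_labels, seed = NULL,
                          sbw_control = ivbalance::sbw_control(),
                          oal_control = ivbalance::oal_control(),
                          scs_width = 5) {
  methods <- match.arg(methods, method_labels, several.ok = TRUE)
  if (!is.null(seed)) {
    config <- scenario_config(config$n, config$J, config$rho, config$theta,
                              config$effect_type, seed = seed,
                              tau = config$tau, beta0 = config$beta0,
                              alpha0 = config$alpha0,
                              sigma_eps = config$sigma_eps)
  }
  data <- simulate_scenario(config)
  purrr::map_dfr(methods, function(m) {
    fit <- tryCatch(
      switch(m,
        Target = ,
        Confounders = ,
        AllCovariates = suppressWarnings(
          estimate_aiptw(data, adjustment_rule(m, config$J), method = m)),
        OAL = suppressWarnings(estimate_oal(data, oal_control)),
        SCS = suppressWarnings(estimate_scs(data, width = scs_width)),
        SBW = suppressWarnings(estimate_sbw(data, sbw_control))
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      tibble::tibble(method = m, estimate = NA_real_, se = NA_real_,
                     ci_low = NA_real_, ci_high = NA_real_,
                     n_covariates = NA_integer_,
                     error = conditionMessage(fit))
    } else {
      tibble::add_column(glance(fit), error = NA_character_)
    }
  })
}

#' Run a scenario for many replicates
#'
#' Replicate `r` uses seed `base_seed + r`, so any single replicate can be
#' re-run in isolation; all requested methods see the same dataset within a
#' replicate.
#'
#' @inheritParams run_replicate
#' @param n_reps Number of Monte Carlo replicates (the study design uses
#'   500).
#' @param base_seed Base of the replicate seed stream; defaults to the
#'   scenario seed.
#' @param progress Print a dot every 50 replicates.
#' @return A tibble of per-replicate estimates (column `replicate` added),
#'   with the scenario config in attribute `config`.
#' @export
run_scenario <- function(config, n_reps = 500, methods = method_labels,
                         base_seed = config$seed, progress = FALSE, ...) {
  out <- purrr::map_dfr(seq_len(n_reps), function(r) {
    if (progress && r %% 50 == 0) cat(".")
    tibble::add_column(
      run_replicate(config, methods, seed = base_seed + r, ...),
      replicate = r, .before = 1)
  })
  if (progress) cat("\n")
  attr(out, "config") <- config
  out
}

#' Summarize Monte Carlo performance
#'
#' Per method: absolute bias, MSE, relative MSE against a reference method,
#' empirical SD of the estimates, average model-based SE, and 95% Wald
#' coverage of the truth, each with a Monte Carlo standard error (bias:
#' EmpSE/sqrt(R); MSE: SD of squared errors/sqrt(R); EmpSE:
#' EmpSE/sqrt(2(R-1)); coverage: sqrt(p(1-p)/R)). Replicates where a method
#' failed are dropped from that method's metrics and counted in `n_fail`.
#'
#' @param estimates Replicate-level tibble from [run_scenario()] (columns
#'   `method`, `estimate`, `se`, `ci_low`, `ci_high`).
#' @param truth True effect (default 1).
#' @param reference Method whose MSE anchors the relative MSE; set `NULL`
#'   to skip.
#' @return A tibble with one row per method.
#' @export
summarize_performance <- function(estimates, truth = 1, reference = "Target") {
  perf <- estimates |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      n_reps = sum(is.finite(.data$estimate)),
      n_fail = sum(!is.finite(.data$estimate)),
      bias_signed = mean(.data$estimate[is.finite(.data$estimate)]) - truth,
      bias = abs(.data$bias_signed),
      mse = mean((.data$estimate - truth)^2, na.rm = TRUE),
      mse_mcse = sd((.data$estimate - truth)^2, na.rm = TRUE) /
        sqrt(.data$n_reps),
      empse = sd(.data$estimate, na.rm = TRUE),
      avgse = mean(.data$se, na.rm = TRUE),
      covrate = mean(.data$ci_low <= truth & truth <= .data$ci_high,
                     na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      bias_mcse = .data$empse / sqrt(.data$n_reps),
      empse_mcse = .data$empse / sqrt(2 * (.data$n_reps - 1)),
      covrate_mcse = sqrt(.data$covrate * (1 - .data$covrate) / .data$n_reps)
    )
  if (!is.null(reference)) {
    if (!reference %in% perf$method) {
      stop("reference method ", reference, " not present.", call. = FALSE)
    }
    ref_mse <- perf$mse[perf$method == reference]
    if (ref_mse <= 0) stop("reference MSE must be positive.", call. = FALSE)
    perf$rmse <- perf$mse / ref_mse
  }
  ord <- match(perf$method, method_labels)
  perf <- perf[order(ord), ]
  cols <- c("method", "n_reps", "n_fail", "bias", "mse", "rmse", "empse",
            "avgse", "covrate", "bias_mcse", "mse_mcse", "empse_mcse",
            "covrate_mcse", "bias_signed")
  perf[intersect(cols, names(perf))]
}

#' The default scenario grid of the simulation study
#'
#' Crossing sample size, number of covariates, covariate correlation,
#' instrument strength and effect type: 32 scenarios.
#'
#' @param n,J,rho,theta,effect_type Vectors crossed into the grid.
#' @return A tibble with one row per scenario.
#' @export
scenario_grid <- function(n = c(500, 2000), J = c(20, 40), rho = c(0, 0.5),
                          theta = c(0.5, 1),
                          effect_type = c("homogeneous", "heterogeneous")) {
  tidyr::expand_grid(n = n, J = J, rho = rho, theta = theta,
                     effect_type = effect_type)
}

#' Run a grid of scenarios
#'
#' Each scenario row gets its own seed stream (`base_seed + 10000 * row`),
#' is replicated `n_reps` times and summarized with
#' [summarize_performance()]; per-scenario tables can be written to disk as
#' CSV alongside the run metadata.
#'
#' @param grid A tibble like [scenario_grid()] (columns `n`, `J`, `rho`,
#'   `theta`, `effect_type`).
#' @param n_reps Replicates per scenario.
#' @param base_seed Master seed of the grid.
#' @param methods Estimators to run.
#' @param dir Optional directory for per-scenario CSV output.
#' @param keep_estimates Keep replicate-level estimates in the result.
#' @param ... Passed to [run_scenario()].
#' @return A tibble: the grid columns plus a nested `performance` list-column
#'   (and `estimates` when `keep_estimates = TRUE`).
#' @export
run_grid <- function(grid, n_reps = 500, base_seed = 1, methods = method_labels,
                     dir = NULL, keep_estimates = FALSE, ...) {
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  res <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    row <- grid[i, ]
    cfg <- scenario_config(row$n, row$J, row$rho, row$theta, row$effect_type,
                           seed = base_seed + 10000L * i)
    est <- run_scenario(cfg, n_reps = n_reps, methods = methods,
                        base_seed = cfg$seed, ...)
    perf <- summarize_performance(est, truth = cfg$tau,
                                  reference = if ("Target" %in% methods)
                                    "Target" else NULL)
    if (!is.null(dir)) {
      tag <- sprintf("n%d_J%d_rho%s_theta%s_%s", row$n, row$J, row$rho,
                     row$theta, row$effect_type)
      readr::write_csv(perf, file.path(dir, paste0("performance_", tag,
                                                   ".csv")))
    }
    out <- tibble::add_column(row, seed = cfg$seed,
                              performance = list(perf))
    if (keep_estimates) out$estimates <- list(est)
    out
  })
  res
}
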