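# Stable balancing weights.
#
# Per treatment group, find nonnegative weights summing to one that minimize
# their variance subject to approximate mean balance of the balance functions
# B_k(X) toward the overall sample means:
#   minimize sum_i (w_i - wbar)^2
#   s.t. |sum_i w_i B_k(x_i) - mean_all B_k| <= delta_k,  sum w = 1,  w >= 0.
# With the sum-to-one constraint the objective equals sum w_i^2 up to a
# constant, so the program is a strictly convex QP with identity Hessian. It
# is solved through its smooth concave dual: eliminating w gives
#   w = max(0, nu - B (alpha - beta)),
#   g(nu, alpha, beta) = nu - alpha'u + beta'l - 0.5 * sum w^2,
# maximized over alpha, beta >= 0 by L-BFGS-B. The dual has dimension
# 2K + 1 regardless of the group size, which keeps the Monte Carlo runs fast;
# infeasibility surfaces as primal constraint violation at the dual optimum.

#' Tuning parameters for stable balancing weights
#'
#' @param delta_multipliers Candidate balance tolerances, expressed as
#'   multiples of the within-group SD of each balance function; strictly
#'   positive and ascending.
#' @param n_bootstrap Number of bootstrap resamples used to pick the
#'   tolerance.
#' @param resolve_per_bootstrap If `TRUE` the weights are re-solved on every
#'   bootstrap resample instead of carrying the original-sample weights
#'   (renormalized within group). Default `FALSE`.
#' @param seed Optional seed for the bootstrap resampling.
#' @return A list of class `sbw_control`.
#' @export
sbw_control <- function(delta_multipliers = c(0.0001, 0.001, 0.002, 0.005,
                                              0.01, 0.02, 0.05, 0.1),
                        n_bootstrap = 200, resolve_per_bootstrap = FALSE,
                        seed = NULL) {
  if (any(delta_multipliers <= 0) || is.unsorted(delta_multipliers)) {
    stop("`delta_multipliers` must be positive and ascending.", call. = FALSE)
  }
  stopifnot(n_bootstrap >= 1)
  structure(list(delta_multipliers = delta_multipliers,
                 n_bootstrap = n_bootstrap,
                 resolve_per_bootstrap = resolve_per_bootstrap,
                 seed = seed),
            class = "sbw_control")
}

#' Minimum-variance balancing weights for one group
#'
#' Solves the group-level quadratic program described above. Infeasibility
#' (the target means cannot be matched within `delta_k` by any convex
#' combination of the group's rows) is reported through the `feasible` flag,
#' not an error, so a tolerance search can skip the candidate.
#'
#' @param B_group Matrix of balance-function values for the units in the
#'   group (rows = units).
#' @param target_means Overall-sample means of the balance functions.
#' @param delta_k Per-function tolerances (nonnegative, recycled if scalar).
#' @param tol Feasibility tolerance on the achieved constraints.
#' @param init Optional warm-start for the dual variables.
#' @return A list: `weights` (sum to 1 within the group when feasible),
#'   `feasible`, `max_violation`, `objective` (variance of the weights),
#'   `dual`.
#' @export
solve_group_weights <- function(B_group, target_means, delta_k, tol = 1e-6,
                                init = NULL) {
  B <- as.matrix(B_group)
  n <- nrow(B)
  K <- ncol(B)
  if (n < 2) stop("group must contain at least 2 units.", call. = FALSE)
  delta_k <- rep_len(delta_k, K)
  if (any(delta_k < 0)) stop("`delta_k` must be nonnegative.", call. = FALSE)
  u <- target_means + delta_k
  l <- target_means - delta_k

  neg_dual <- function(p) {
    w <- pmax(0, p[1] - drop(B %*% (p[2:(K + 1)] - p[(K + 2):(2 * K + 1)])))
    -(p[1] - sum(p[2:(K + 1)] * u) + sum(p[(K + 2):(2 * K + 1)] * l) -
        0.5 * sum(w^2))
  }
  neg_grad <- function(p) {
    w <- pmax(0, p[1] - drop(B %*% (p[2:(K + 1)] - p[(K + 2):(2 * K + 1)])))
    Bw <- drop(crossprod(B, w))
    -c(1 - sum(w), Bw - u, l - Bw)
  }
  p0 <- init %||% rep(0, 2 * K + 1)
  opt <- stats::optim(p0, neg_dual, neg_grad, method = "L-BFGS-B",
                      lower = c(-Inf, rep(0, 2 * K)),
                      control = list(maxit = 2000L, factr = 10))
  w <- pmax(0, opt$par[1] -
              drop(B %*% (opt$par[2:(K + 1)] - opt$par[(K + 2):(2 * K + 1)])))
  s <- sum(w)
  viol_sum <- abs(s - 1)
  if (s > 0) w <- w / s
  Bw <- drop(crossprod(B, w))
  viol <- max(c(viol_sum, Bw - u, l - Bw, 0))
  feasible <- s > 0 && viol <= tol
  list(weights = w, feasible = feasible, max_violation = viol,
       objective = sum((w - mean(w))^2), dual = opt$par)
}

#' Candidate balance tolerances per group
#'
#' `delta_k(z) = multiplier * S_k^z`, where `S_k^z` is the unweighted SD of
#' balance function `k` within group `z`.
#'
#' @param B Balance-function matrix for the full sample.
#' @param Z Binary group indicator.
#' @param multipliers Positive multipliers.
#' @return A tibble with columns `multiplier`, `group`, `k`, `sd`, `delta`.
#' @export
delta_candidates <- function(B, Z, multipliers) {
  B <- as.matrix(B)
  sds <- lapply(c(0, 1), function(z) apply(B[Z == z, , drop = FALSE], 2, sd))
  for (z in 1:2) {
    bad <- which(sds[[z]] == 0)
    if (length(bad)) {
      stop("balance function ", paste(colnames(B)[bad], collapse = ", "),
           " has zero SD in group ", z - 1, call. = FALSE)
    }
  }
  tidyr::expand_grid(multiplier = multipliers, group = c(0L, 1L),
                     k = seq_len(ncol(B))) |>
    dplyr::mutate(sd = purrr::map2_dbl(.data$group, .data$k,
                                       ~ sds[[.x + 1]][.y]),
                  delta = .data$multiplier * .data$sd)
}

# Solve both groups across the multiplier grid, warm-starting each solve from
# the previous (larger-delta) solution.
solve_delta_grid <- function(B, Z, multipliers, target) {
  sds <- lapply(c(0, 1), function(z) apply(B[Z == z, , drop = FALSE], 2, sd))
  out <- vector("list", length(multipliers))
  for (gi in 1:2) {
    z <- gi - 1L
    Bg <- B[Z == z, , drop = FALSE]
    init <- NULL
    for (mi in rev(seq_along(multipliers))) {
      sol <- solve_group_weights(Bg, target, multipliers[mi] * sds[[gi]],
                                 init = init)
      if (sol$feasible) init <- sol$dual
      out[[mi]][[gi]] <- sol
    }
  }
  out
}

#' Bootstrap selection of the balance tolerance
#'
#' For each feasible tolerance, weights are solved on the original sample;
#' bootstrap resamples (units drawn with replacement, carrying their
#' original weights renormalized within group) yield the summed standardized
#' absolute distances (ASD) between weighted group means and the original
#' overall means; the tolerance minimizing the bootstrap-averaged ASD wins,
#' ties going to the smaller tolerance.
#'
#' @param X Covariate (balance-function) matrix or data frame.
#' @param Z Binary treatment vector.
#' @param control An [sbw_control()].
#' @return A list: `selected_multiplier`, `table` (per-tolerance tibble with
#'   feasibility flags and mean bootstrap ASD), `solutions` (per-tolerance,
#'   per-group solver output).
#' @export
bootstrap_select_delta <- function(X, Z, control = sbw_control()) {
  B <- as.matrix(X)
  n <- nrow(B)
  mult <- control$delta_multipliers
  target <- colMeans(B)
  sds <- lapply(c(0, 1), function(z) apply(B[Z == z, , drop = FALSE], 2, sd))
  sols <- solve_delta_grid(B, Z, mult, target)

  if (!is.null(control$seed)) set.seed(control$seed)
  boot_idx <- replicate(control$n_bootstrap, sample.int(n, n, replace = TRUE),
                        simplify = FALSE)

  asd_for <- function(sol_pair, idx) {
    wfull <- numeric(n)
    wfull[Z == 0] <- sol_pair[[1]]$weights
    wfull[Z == 1] <- sol_pair[[2]]$weights
    zz <- Z[idx]
    ww <- wfull[idx]
    Bb <- B[idx, , drop = FALSE]
    total <- 0
    for (gi in 1:2) {
      sel <- zz == (gi - 1L)
      s <- sum(ww[sel])
      if (s == 0) return(NA_real_)
      gm <- drop(crossprod(Bb[sel, , drop = FALSE], ww[sel])) / s
      total <- total + sum(abs(gm - target) / sds[[gi]])
    }
    total
  }

  mean_asd <- rep(NA_real_, length(mult))
  for (mi in seq_along(mult)) {
    pair <- sols[[mi]]
    if (!pair[[1]]$feasible || !pair[[2]]$feasible) next
    if (control$resolve_per_bootstrap) {
      vals <- vapply(boot_idx, function(idx) {
        Bb <- B[idx, , drop = FALSE]
        zz <- Z[idx]
        resolved <- lapply(1:2, function(gi) {
          solve_group_weights(Bb[zz == (gi - 1L), , drop = FALSE], target,
                              mult[mi] * sds[[gi]])
        })
        if (!all(vapply(resolved, `[[`, TRUE, "feasible"))) return(NA_real_)
        total <- 0
        for (gi in 1:2) {
          gm <- drop(crossprod(Bb[zz == (gi - 1L), , drop = FALSE],
                               resolved[[gi]]$weights))
          total <- total + sum(abs(gm - target) / sds[[gi]])
        }
        total
      }, numeric(1))
    } else {
      vals <- vapply(boot_idx, function(idx) asd_for(pair, idx), numeric(1))
    }
    mean_asd[mi] <- mean(vals, na.rm = TRUE)
  }

  feasible <- !is.na(mean_asd)
  if (!any(feasible)) {
    stop("no balance tolerance was feasible; consider larger ",
         "`delta_multipliers`.", call. = FALSE)
  }
  best <- which(mean_asd == min(mean_asd, na.rm = TRUE))[1]
  tab <- tibble::tibble(
    multiplier = mult,
    feasible_control = vapply(sols, function(p) p[[1]]$feasible, TRUE),
    feasible_treated = vapply(sols, function(p) p[[2]]$feasible, TRUE),
    mean_bootstrap_asd = mean_asd,
    selected = seq_along(mult) == best
  )
  list(selected_multiplier = mult[best], table = tab, solutions = sols,
       target = target, group_sds = sds)
}

#' Stable-balancing-weights AIPTW estimate
#'
#' Solves the per-group minimum-variance balancing weights at the
#' bootstrap-selected tolerance, rescales them from the within-group
#' (sum-to-one) scale to the IPW scale by multiplying by `n`, and combines
#' them with OLS outcome predictions on the full covariate set in the AIPTW
#' estimator.
#'
#' @param data A data frame with columns `Y`, `Z`, `X1`..`XJ`.
#' @param control An [sbw_control()].
#' @param balance Optional function mapping the covariate matrix to the
#'   matrix of balance functions; defaults to the raw covariates.
#' @return An object of class `sbw_fit` (also `aiptw_fit`): the usual effect
#'   fields plus `selected_multiplier`, `delta_table`, `weights_group` (a
#'   per-unit tibble), `achieved_imbalance`.
#' @export
#' @examples
#' dat <- simulate_scenario(scenario_config(300, J = 20, seed = 11))
#' fit <- estimate_sbw(dat, sbw_control(n_bootstrap = 20, seed = 1))
#' glance(fit)
estimate_sbw <- function(data, control = sbw_control(), balance = NULL) {
  X <- covariate_matrix(data)
  B <- if (is.null(balance)) X else as.matrix(balance(X))
  if (is.null(colnames(B))) colnames(B) <- paste0("B", seq_len(ncol(B)))
  Z <- data$Z
  Y <- data$Y
  n <- nrow(B)

  sel <- bootstrap_select_delta(B, Z, control)
  mi <- which(control$delta_multipliers == sel$selected_multiplier)
  pair <- sel$solutions[[mi]]

  wfull <- numeric(n)
  wfull[Z == 0] <- pair[[1]]$weights
  wfull[Z == 1] <- pair[[2]]$weights
  w_ipw <- new_weight_vector(wfull * n, scale = "ipw", source = "sbw")

  om <- fit_outcome_model(X, Z, Y)
  tau <- aiptw(Y, Z, w_ipw, om$m1, om$m0)
  se <- influence_se(Y, Z, w_ipw, om$m1, om$m0, tau)

  imb <- purrr::map_dfr(1:2, function(gi) {
    z <- gi - 1L
    gm <- drop(crossprod(B[Z == z, , drop = FALSE], wfull[Z == z])) /
      sum(wfull[Z == z])
    tibble::tibble(group = z, balance_function = colnames(B),
                   imbalance = abs(gm - sel$target),
                   delta = sel$selected_multiplier * sel$group_sds[[gi]])
  })

  new_effect_fit(
    tau, se, "SBW", colnames(X), class = "sbw_fit",
    extra = list(selected_multiplier = sel$selected_multiplier,
                 delta_table = sel$table,
                 weights_group = tibble::tibble(
                   unit = seq_len(n), group = Z, weight_group = wfull,
                   weight_ipw = wfull * n),
                 achieved_imbalance = imb, weights = w_ipw,
                 outcome_coef = om$coef)
  )
}

#' Tidy a stable-balancing-weights fit
#'
#' Per-unit weights on both scales (within-group sum-to-one and IPW).
#'
#' @param x An `sbw_fit`.
#' @param ... Unused.
#' @return A tibble with columns `unit`, `group`, `weight_group`,
#'   `weight_ipw`.
#' @export
tidy.sbw_fit <- function(x, ...) x$weights_group
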