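# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Brute-force AIPTW: explicit loop over units, no vectorization shared with
# aiptw().
aiptw_loop <- function(Y, Z, w, m1, m0) {
  total <- 0
  for (i in seq_along(Y)) {
    m_obs <- if (Z[i] == 1) m1[i] else m0[i]
    total <- total + (2 * Z[i] - 1) * w[i] * (Y[i] - m_obs) + m1[i] - m0[i]
  }
  total / length(Y)
}

influence_se_loop <- function(Y, Z, w, m1, m0, tau) {
  psi <- numeric(length(Y))
  for (i in seq_along(Y)) {
    m_obs <- if (Z[i] == 1) m1[i] else m0[i]
    psi[i] <- (2 * Z[i] - 1) * w[i] * (Y[i] - m_obs) + m1[i] - m0[i] - tau
  }
  sqrt(sum((psi - mean(psi))^2) / (length(Y) - 1)) / sqrt(length(Y))
}

# Proximal-gradient solver for the weighted-L1 penalized logistic likelihood
# (mean negative log-likelihood + (lambda/n) * sum omega_j |beta_j|).
prox_penalized_logistic <- function(X, Z, lambda, omega, iters = 50000) {
  n <- nrow(X)
  p <- ncol(X)
  b0 <- 0
  b <- rep(0, p)
  L <- 0.25 * max(eigen(crossprod(cbind(1, X)) / n,
                        symmetric = TRUE)$values)
  step <- 1 / L
  for (it in seq_len(iters)) {
    mu <- plogis(b0 + drop(X %*% b))
    b0 <- b0 - step * mean(mu - Z)
    bt <- b - step * drop(crossprod(X, mu - Z)) / n
    b <- sign(bt) * pmax(0, abs(bt) - step * (lambda / n) * omega)
  }
  unname(c(b0, b))
}

# Dense grid search over the 2-simplex for a 3-unit balancing problem.
simplex_grid_qp <- function(B, target, delta, step = 1e-3) {
  best <- Inf
  best_w <- NULL
  for (w1 in seq(0, 1, by = step)) {
    for (w2 in seq(0, 1 - w1, by = step)) {
      w <- c(w1, w2, 1 - w1 - w2)
      if (all(abs(drop(crossprod(B, w)) - target) <= delta)) {
        obj <- sum((w - mean(w))^2)
        if (obj < best) {
          best <- obj
          best_w <- w
        }
      }
    }
  }
  list(weights = best_w, objective = best)
}

make_scenario_data <- function(n = 300, J = 20, rho = 0, theta = 0.5,
                               effect_type = "homogeneous", seed = 1,
                               sigma_eps = 2) {
  simulate_scenario(scenario_config(n, J, rho, theta, effect_type,
                                    seed = seed, sigma_eps = sigma_eps))
}
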