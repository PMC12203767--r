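test_that("gamma calibration solves lambda * n^(gamma/2 - 1) = n^2", {
  n <- 500
  expect_equal(gamma_for_lambda(n^-2, n), 10)
  expect_equal(gamma_for_lambda(n^0.49, n), 5.02)
  expect_equal(gamma_for_lambda(n^-10, n), 26)
  for (a in c(-5, -0.75, 0.25)) {
    g <- gamma_for_lambda(n^a, n)
    expect_equal((n^a) * n^(g / 2 - 1), n^2, tolerance = 1e-8)
  }
  expect_error(gamma_for_lambda(1, 1), "exceed 1")
})

test_that("penalty weights invert outcome associations and cap at omega_cap", {
  expect_equal(penalty_weights(1, 2), 1)
  expect_equal(penalty_weights(0.5, 2), 4)
  expect_equal(penalty_weights(0, 7, omega_cap = 1e8), 1e8)
  expect_equal(penalty_weights(c(-0.5, 2), 2), c(4, 0.25))
  expect_error(penalty_weights(1, 0.5), "exceed 1")
})

test_that("standardization centers, scales and records the transform", {
  set.seed(31)
  X <- cbind(a = 2 * rnorm(5000), b = rnorm(5000) + 3)
  s <- standardize(X)
  expect_equal(unname(s$sds["a"]), 2, tolerance = 0.1)
  expect_equal(unname(colMeans(s$X_std)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(s$X_std, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_error(standardize(cbind(ok = rnorm(5), flat = 1)), "flat")
})

test_that("outcome associations recover the generating coefficients", {
  set.seed(41)
  X <- matrix(rnorm(5000 * 4), ncol = 4)
  Z <- rbinom(5000, 1, 0.5)
  a <- outcome_association_coefs(X, Z, Z + X[, 1])  # noise-free, only X1
  expect_equal(unname(a), c(1, 0, 0, 0), tolerance = 1e-10)

  d <- make_scenario_data(n = 1e5, J = 8, seed = 43)
  s <- standardize(covariate_matrix(d))
  a2 <- outcome_association_coefs(s$X_std, d$Z, d$Y)
  expect_equal(unname(a2), c(1, 1, 1, 1, 0, 0, 0, 0), tolerance = 0.05)
})

test_that("penalized logistic fit matches a proximal-gradient oracle", {
  set.seed(51)
  n <- 200
  X <- scale(matrix(rnorm(n * 3), ncol = 3))
  attributes(X)[c("scaled:center", "scaled:scale")] <- NULL
  colnames(X) <- paste0("X", 1:3)
  Z <- rbinom(n, 1, plogis(0.3 + X %*% c(0.8, -0.5, 0)))
  lambda <- 5
  omega <- c(1, 2, 0.5)
  cf <- fit_penalized_logistic(X, Z, lambda, omega)
  oracle <- prox_penalized_logistic(X, Z, lambda, omega)
  expect_equal(unname(cf), oracle, tolerance = 1e-4)
})

test_that("penalized fit hits the unpenalized and full-shrinkage limits", {
  set.seed(52)
  n <- 300
  X <- matrix(rnorm(n * 3), ncol = 3)
  colnames(X) <- paste0("X", 1:3)
  Z <- rbinom(n, 1, plogis(X %*% c(1, -1, 0)))
  ml <- fit_logistic_ps(X, Z)
  cf0 <- fit_penalized_logistic(X, Z, lambda = 0, omega = rep(1, 3))
  expect_equal(unname(cf0), unname(c(ml$intercept, ml$coef)),
               tolerance = 1e-4)
  cf_inf <- fit_penalized_logistic(X, Z, lambda = 1e6, omega = rep(1, 3))
  expect_equal(unname(cf_inf[-1]), c(0, 0, 0))
  expect_equal(unname(cf_inf[1]), qlogis(mean(Z)), tolerance = 1e-3)
})

test_that("L1 norm of the fit shrinks monotonically in lambda", {
  set.seed(53)
  n <- 250
  X <- matrix(rnorm(n * 4), ncol = 4)
  colnames(X) <- paste0("X", 1:4)
  Z <- rbinom(n, 1, plogis(X %*% c(1, 0.5, 0, 0)))
  omega <- rep(1, 4)
  norms <- vapply(c(0.1, 1, 5, 20, 100), function(l) {
    sum(abs(fit_penalized_logistic(X, Z, l, omega)[-1]))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-6))
})

test_that("wAMD weights imbalance by outcome associations", {
  X <- cbind(X1 = 1:6, X2 = c(0, 1, 0, 1, 0, 1))
  Z <- c(1, 1, 1, 0, 0, 0)
  ps <- rep(0.5, 6)  # constant -> Hajek means equal unweighted group means
  expect_equal(wamd(X, Z, ps, c(2, 3)), 2 * 3 + 3 * (1 / 3))
  expect_equal(wamd(X, Z, ps, c(0, 0)), 0)
  # perfectly balanced groups give zero regardless of alpha
  Xb <- cbind(X1 = c(1, 2, 1, 2), X2 = c(0, 5, 0, 5))
  expect_equal(wamd(Xb, c(1, 1, 0, 0), rep(0.5, 4), c(3, 7)), 0)
  # linear in |alpha|, invariant to covariate relabeling
  expect_equal(wamd(X, Z, ps, c(4, 6)), 2 * wamd(X, Z, ps, c(2, 3)))
  expect_equal(wamd(X[, 2:1], Z, ps, c(3, 2)), wamd(X, Z, ps, c(2, 3)))
})

test_that("OAL selects confounders and outcome predictors, drops instruments", {
  picks <- matrix(0, 10, 6)
  for (r in 1:10) {
    d <- make_scenario_data(n = 500, J = 20, theta = 1, seed = 600 + r)
    fit <- estimate_oal(d)
    picks[r, ] <- paste0("X", 1:6) %in% fit$selected_set
  }
  freq <- colMeans(picks)
  expect_true(all(freq[1:4] >= 0.8))          # X1..X4 nearly always kept
  expect_true(mean(freq[5:6]) < mean(freq[1:4]))  # instruments kept less
})

test_that("constant outcomes force full shrinkage and the smallest lambda", {
  d <- make_scenario_data(n = 200, J = 6, seed = 61)
  d$Y <- rep(2, nrow(d))
  fit <- suppressWarnings(estimate_oal(d))
  # all outcome associations are exactly zero, so every lambda ties at
  # wAMD ~ 0 and the smallest lambda wins deterministically
  expect_equal(fit$selected_exponent, min(oal_control()$lambda_exponents))
  expect_true(all(fit$path$wamd < 1e-10))
})

test_that("the OAL path is exportable and internally consistent", {
  d <- make_scenario_data(n = 300, J = 8, seed = 62)
  fit <- estimate_oal(d)
  td <- tidy(fit)
  expect_equal(nrow(td), 9)
  expect_true(all(c("lambda_exponent", "gamma", "wamd", "n_nonzero")
                  %in% names(td)))
  expect_equal(fit$path$wamd[fit$path$lambda_exponent ==
                               fit$selected_exponent],
               min(fit$path$wamd))
  expect_equal(sum(fit$coef_std[-1] != 0), length(fit$selected_set))
})
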