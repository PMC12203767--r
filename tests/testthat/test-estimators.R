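test_that("logistic PS fit recovers null and true coefficients", {
  set.seed(101)
  X <- matrix(rnorm(4000 * 3), ncol = 3)
  Z <- rbinom(4000, 1, 0.4)  # independent of X
  fit <- fit_logistic_ps(X, Z)
  expect_true(all(abs(fit$coef) < 0.1))
  expect_equal(mean(fit$fitted_ps), mean(Z), tolerance = 0.01)

  d <- make_scenario_data(n = 1e5, J = 6, theta = 1, seed = 55)
  fit2 <- fit_logistic_ps(covariate_matrix(d), d$Z)
  expect_equal(unname(fit2$coef), c(0.5, 0.5, 0, 0, 1, 1), tolerance = 0.05)
  expect_error(fit_logistic_ps(X, rep(1, 4000)), "constant")
})

test_that("separation is flagged and fitted probabilities stay in (0,1)", {
  X <- matrix(c(-2, -1, 1, 2), 4, 1)
  Z <- c(0, 0, 1, 1)
  expect_warning(fit <- fit_logistic_ps(X, Z), "separation")
  expect_true(all(fit$fitted_ps > 0 & fit$fitted_ps < 1))
})

test_that("outcome model is a joint OLS with constant treatment contrast", {
  om <- fit_outcome_model(matrix(rnorm(20), 10, 2), rep(0:1, 5), rep(3, 10))
  expect_equal(om$m1, rep(3, 10))
  expect_equal(om$m0, rep(3, 10))

  # hand OLS on the 4-point design: Z coefficient is 1
  om2 <- fit_outcome_model(matrix(nrow = 4, ncol = 0), Z = c(0, 1, 0, 1),
                           Y = c(0, 1, 1, 2))
  expect_equal(unname(om2$coef["Z"]), 1)
  expect_equal(om2$m1 - om2$m0, rep(1, 4))

  # noise-free homogeneous data: exact recovery of the unit effect
  d <- make_scenario_data(n = 200, J = 6, seed = 3, sigma_eps = 0)
  om3 <- fit_outcome_model(covariate_matrix(d), d$Z, d$Y)
  expect_equal(unname(om3$coef["Z"]), 1, tolerance = 1e-10)

  # aliased column dropped with a warning
  X <- cbind(a = rnorm(30), b = 0)
  expect_warning(fit_outcome_model(X, rbinom(30, 1, 0.5), rnorm(30)),
                 "aliased")
})

test_that("IPW weights invert the propensity of the received arm", {
  w <- ipw_weights(rep(0.5, 4), c(1, 1, 0, 0))
  expect_equal(w$weights, rep(2, 4))
  expect_equal(ipw_weights(0.1, 1)$weights, 10)
  expect_equal(ipw_weights(0.1, 0)$weights, 10 / 9)
  expect_gte(min(ipw_weights(c(1e-6, 1 - 1e-6), c(0, 1))$weights), 1)
  expect_error(ipw_weights(c(0, 0.5), c(1, 0)), "strictly inside")
})

test_that("AIPTW matches the hand-worked example and a brute-force loop", {
  Y <- c(1, 3, 0, 2)
  Z <- c(1, 1, 0, 0)
  w <- rep(2, 4)  # e = 0.5 everywhere
  m1 <- rep(2, 4)
  m0 <- rep(1, 4)
  expect_equal(aiptw(Y, Z, w, m1, m0), 1)
  expect_equal(influence_se(Y, Z, w, m1, m0, 1), sqrt(16 / 3) / 2)

  # oracle equivalence on random toys
  set.seed(77)
  for (r in 1:5) {
    n <- 30
    Y <- rnorm(n); Z <- rbinom(n, 1, 0.5)
    ps <- runif(n, 0.2, 0.8)
    w <- ifelse(Z == 1, 1 / ps, 1 / (1 - ps))
    m1 <- rnorm(n); m0 <- rnorm(n)
    tau <- aiptw(Y, Z, w, m1, m0)
    expect_equal(tau, aiptw_loop(Y, Z, w, m1, m0))
    expect_equal(influence_se(Y, Z, w, m1, m0, tau),
                 influence_se_loop(Y, Z, w, m1, m0, tau))
  }
})

test_that("AIPTW reduces correctly in degenerate configurations", {
  set.seed(12)
  n <- 50
  Z <- rbinom(n, 1, 0.5)
  m1 <- rnorm(n); m0 <- rnorm(n)
  Y <- ifelse(Z == 1, m1, m0)  # predictions exact per arm
  w <- runif(n, 1, 5)
  expect_equal(aiptw(Y, Z, w, m1, m0), mean(m1 - m0))
  # m1 = m0 = 0 and e = 0.5: reduces to mean(2 (2Z-1) Y)
  Y2 <- rnorm(n)
  expect_equal(aiptw(Y2, Z, rep(2, n), rep(0, n), rep(0, n)),
               mean(2 * (2 * Z - 1) * Y2))
})

test_that("group-scale weights are rejected until rescaled", {
  w <- ivbalance:::new_weight_vector(rep(0.1, 10), scale = "hajek_group",
                                     source = "sbw")
  expect_error(aiptw(rnorm(10), rbinom(10, 1, 0.5), w, rnorm(10), rnorm(10)),
               "IPW scale")
})

test_that("Wald intervals use the normal quantile", {
  expect_equal(wald_ci(1, 0), c(ci_low = 1, ci_high = 1))
  expect_equal(wald_ci(0, 1), c(ci_low = -1.959964, ci_high = 1.959964),
               tolerance = 1e-6)
  expect_error(wald_ci(0, 1, level = 1.2), "level")
  expect_error(wald_ci(0, -1), "nonnegative")
})

test_that("estimate_aiptw pipes data to a tidy effect estimate", {
  d <- make_scenario_data(n = 800, J = 8, seed = 14)
  fit <- estimate_aiptw(d, paste0("X", 1:4), method = "Target")
  g <- glance(fit)
  expect_named(g, c("method", "estimate", "se", "ci_low", "ci_high",
                    "n_covariates"))
  expect_true(g$ci_low <= g$estimate && g$estimate <= g$ci_high)
  expect_equal(g$ci_high - g$estimate, 1.959964 * g$se, tolerance = 1e-6)
  td <- tidy(fit)
  expect_setequal(unique(td$model), c("propensity", "outcome"))
})
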