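test_that("slack constraints give uniform weights", {
  set.seed(71)
  B <- matrix(rnorm(40 * 3), ncol = 3)
  sol <- solve_group_weights(B, colMeans(B), delta_k = 100)
  expect_true(sol$feasible)
  expect_equal(sol$weights, rep(1 / 40, 40), tolerance = 1e-5)
})

test_that("exact balance with two units is the unique feasible point", {
  sol <- solve_group_weights(matrix(c(0, 1), 2, 1), target_means = 0.75,
                             delta_k = 0)
  expect_true(sol$feasible)
  expect_equal(sol$weights, c(0.25, 0.75), tolerance = 1e-6)
})

test_that("the QP solution matches a simplex grid-search oracle", {
  set.seed(72)
  B <- matrix(c(0, 1, 2, 1, 0, 1), 3, 2)
  target <- c(1.2, 0.4)
  delta <- c(0.3, 0.3)
  sol <- solve_group_weights(B, target, delta)
  oracle <- simplex_grid_qp(B, target, delta, step = 5e-4)
  expect_true(sol$feasible)
  expect_equal(sol$objective, oracle$objective, tolerance = 1e-3)
  expect_equal(sol$weights, oracle$weights, tolerance = 0.01)
})

test_that("the dual solver agrees with an interior-point QP solver", {
  skip_if_not_installed("kernlab")
  set.seed(73)
  n <- 120
  K <- 6
  B <- matrix(rnorm(n * K), n, K)
  target <- colMeans(B) + 0.05
  delta <- rep(0.03, K)
  sol <- solve_group_weights(B, target, delta)
  ip <- kernlab::ipop(c = rep(0, n), H = diag(n),
                      A = rbind(rep(1, n), t(B)),
                      b = c(1, target - delta), l = rep(0, n),
                      u = rep(1, n), r = c(0, 2 * delta), sigf = 7)
  expect_true(sol$feasible)
  wi <- kernlab::primal(ip)
  expect_equal(sol$weights, wi, tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(sum((sol$weights - mean(sol$weights))^2),
               sum((wi - mean(wi))^2), tolerance = 1e-2)
})

test_that("balance constraints hold and the optimum tightens with delta", {
  set.seed(74)
  B <- matrix(rnorm(80 * 4), ncol = 4)
  target <- colMeans(B) + 0.1
  objs <- vapply(c(0.02, 0.05, 0.1, 0.5), function(dl) {
    sol <- solve_group_weights(B, target, rep(dl, 4))
    expect_true(sol$feasible)
    expect_true(all(abs(drop(crossprod(B, sol$weights)) - target) <=
                      dl + 1e-6))
    sol$objective
  }, numeric(1))
  # smaller tolerance -> larger weight variance
  expect_true(all(diff(objs) <= 1e-8))
})

test_that("infeasible targets are signalled, not thrown", {
  set.seed(75)
  B <- matrix(rnorm(30 * 2), ncol = 2)
  sol <- solve_group_weights(B, colMeans(B) + 10, delta_k = 1e-4)
  expect_false(sol$feasible)
})

test_that("delta candidates scale with the within-group SD", {
  set.seed(76)
  B <- cbind(B1 = rnorm(100), B2 = 10 * rnorm(100))
  Z <- rep(0:1, 50)
  tab <- delta_candidates(B, Z, multipliers = c(0.01, 0.1))
  expect_equal(nrow(tab), 2 * 2 * 2)
  expect_true(all(tab$delta > 0))
  expect_equal(tab$delta, tab$multiplier * tab$sd)
  Bflat <- cbind(B1 = rnorm(100), B2 = rep(Z, 1))  # constant within group
  expect_error(delta_candidates(Bflat, Z, 0.01), "zero SD")
})

test_that("bootstrap tolerance selection is deterministic and skips
           infeasible candidates", {
  d <- make_scenario_data(n = 200, J = 8, rho = 0.5, theta = 1, seed = 81)
  ctrl <- sbw_control(n_bootstrap = 30, seed = 5)
  s1 <- bootstrap_select_delta(covariate_matrix(d), d$Z, ctrl)
  s2 <- bootstrap_select_delta(covariate_matrix(d), d$Z, ctrl)
  expect_identical(s1$selected_multiplier, s2$selected_multiplier)
  expect_identical(s1$table, s2$table)
  feas <- s1$table$feasible_control & s1$table$feasible_treated
  expect_true(all(is.na(s1$table$mean_bootstrap_asd[!feas])))
  expect_true(s1$table$selected[which.min(s1$table$mean_bootstrap_asd)])
})

test_that("SBW weights approximate true inverse-probability weights", {
  d <- make_scenario_data(n = 5000, J = 20, rho = 0, theta = 0.5, seed = 82)
  fit <- estimate_sbw(d, sbw_control(n_bootstrap = 10, seed = 2))
  w_true <- ifelse(d$Z == 1, 1 / true_ps(d), 1 / (1 - true_ps(d)))
  expect_gt(cor(fit$weights$weights, w_true, method = "spearman"), 0.9)
})

test_that("SBW estimate carries group-normalized weights and balance", {
  d <- make_scenario_data(n = 300, J = 8, rho = 0.5, theta = 1, seed = 83)
  fit <- estimate_sbw(d, sbw_control(n_bootstrap = 20, seed = 3))
  w <- tidy(fit)
  expect_equal(sum(w$weight_group[w$group == 0]), 1, tolerance = 1e-6)
  expect_equal(sum(w$weight_group[w$group == 1]), 1, tolerance = 1e-6)
  expect_true(all(w$weight_group >= 0))
  expect_equal(w$weight_ipw, w$weight_group * nrow(d))
  # achieved imbalance within the selected tolerance (plus solver slack)
  expect_true(all(fit$achieved_imbalance$imbalance <=
                    fit$achieved_imbalance$delta + 1e-6))
  g <- glance(fit)
  expect_true(is.finite(g$estimate) && g$se > 0)
})
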