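# ivbalance

Instrumental variables (IVs) — covariates that predict treatment but not the
outcome — are a quiet hazard in propensity-score weighting: they push
propensity scores toward 0 and 1, blow up inverse-probability weights, and
can amplify bias. `ivbalance` is a simulation and estimation toolkit for
epidemiologists and biostatisticians comparing three data-adaptive defenses
around a common doubly robust estimator:

* **OAL** — the outcome-adaptive lasso: a weighted-L1 penalized logistic
  propensity model with penalties `ω_j = |α̃_j|^(−γ)` driven by
  outcome-model coefficients, tuned over `λ = n^a` by the weighted absolute
  mean difference;
* **SBW** — stable balancing weights: per-group minimum-variance weights
  under approximate mean-balance constraints toward the overall sample
  means, solved as a quadratic program with the tolerance chosen by
  bootstrap;
* **SCS** — stable confounder selection: covariates ranked by
  `min(|z|, |t|)` association strength, AIPTW traced along nested top-k
  sets, and the smallest set stable under an inverse-variance-weighted
  moving average (window 5) selected.

All three feed the augmented inverse-probability-of-treatment weighting
(AIPTW) estimator

```
τ̂ = n⁻¹ Σᵢ [ (2Zᵢ−1) Ŵᵢ (Yᵢ − m̂_{Zᵢ}(Xᵢ)) + m̂₁(Xᵢ) − m̂₀(Xᵢ) ],
Ŵᵢ = Zᵢ/êᵢ + (1−Zᵢ)/(1−êᵢ),
```

with influence-function standard errors and Wald intervals. The package
also ships the study's synthetic data-generating process (equicorrelated
Gaussian covariates; confounders X1–X2, outcome-only predictors X3–X4, IVs
X5–X6 of strength θ, spurious covariates beyond; true ATE = 1), a Monte
Carlo harness (bias, MSE, relative MSE, EmpSE, AvgSE, coverage, with Monte
Carlo SEs), and weighting diagnostics (effective sample size, maximum
normalized weight, population standardized differences).

## Worked example

```r
library(ivbalance)

# a hard scenario: correlated covariates, strong IVs
cfg <- scenario_config(n = 1000, J = 20, rho = 0.5, theta = 1, seed = 3)
dat <- simulate_scenario(cfg)
extreme_ps_fraction(true_ps(dat))
#> [1] 0.374

fit_target <- estimate_aiptw(dat, paste0("X", 1:4), method = "Target")
fit_oal    <- estimate_oal(dat)
fit_sbw    <- estimate_sbw(dat, sbw_control(n_bootstrap = 50, seed = 2))
fit_scs    <- estimate_scs(dat)

dplyr::bind_rows(lapply(list(fit_target, fit_oal, fit_sbw, fit_scs), glance))
#> # A tibble: 4 × 6
#>   method estimate    se ci_low ci_high n_covariates
#>   <chr>     <dbl> <dbl>  <dbl>   <dbl>        <int>
#> 1 Target     1.03 0.160  0.720    1.35            4
#> 2 OAL        1.03 0.160  0.720    1.35            4
#> 3 SBW        1.08 0.164  0.759    1.40           20
#> 4 SCS        1.14 0.185  0.776    1.50           16
```

All four estimators cover the true ATE of 1 even though 37% of the true
propensity scores sit outside `[0.1, 0.9]`. In this draw OAL's selected set
(`fit_oal$selected_set`) is exactly `X1–X4` — the confounders plus outcome
predictors, with the IVs shrunk away — so it coincides with the Target
benchmark; SBW balances all 20 covariates without ever inverting a fitted
propensity score.

Monte Carlo comparison of methods in a scenario:

```r
est <- run_scenario(scenario_config(500, J = 20, rho = 0.5, theta = 0.5,
                                    seed = 1),
                    n_reps = 200, methods = c("Target", "SBW"),
                    sbw_control = sbw_control(n_bootstrap = 50))
summarize_performance(est)[, c("method", "bias", "mse", "rmse", "covrate")]
#> # A tibble: 2 × 5
#>   method    bias    mse  rmse covrate
#>   <chr>    <dbl>  <dbl> <dbl>   <dbl>
#> 1 Target 0.0118  0.0544 1       0.955
#> 2 SBW    0.00621 0.0465 0.854   0.94
```

`rmse < 1` says SBW beats even the oracle adjustment set here — limited
overlap makes inverting true-model propensity scores costly, while the
balancing weights stay stable. `autoplot()` methods display the OAL wAMD
path, the SBW tolerance search, and the SCS stability path;
`weighting_diagnostics()` summarizes the resulting weights.

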