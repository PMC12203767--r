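---
title: "Handling instrumental variables in propensity-score weighting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Handling instrumental variables in propensity-score weighting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivbalance)
library(dplyr)
```

## The problem

Weighting on the propensity score $e(X) = \Pr(Z = 1 \mid X)$ identifies the
average treatment effect (ATE) under exchangeability and positivity, but the
estimators are fragile when propensity scores approach 0 or 1. Instrumental
variables (IVs) — covariates that predict treatment but not the outcome — are
a common cause of such *limited overlap*: including them in the propensity
model pushes fitted scores toward the boundaries, inflates the
inverse-probability weights, and can amplify bias from residual
confounding. Spurious covariates (related to neither treatment nor outcome)
add estimation noise on top. In practice one rarely knows a priori which
measured covariates are IVs, so the adjustment set has to be chosen
data-adaptively.

`ivbalance` implements and compares three adaptive strategies around a common
doubly robust estimator:

* **OAL** — the outcome-adaptive lasso: a penalized logistic propensity
  model whose covariate-specific penalties are driven by outcome-model
  coefficients, so IVs and spurious covariates are shrunk out of the model;
* **SBW** — stable balancing weights: skip the propensity model entirely and
  solve for minimum-variance weights under approximate mean-balance
  constraints;
* **SCS** — stable confounder selection: rank covariates by their joint
  association with treatment and outcome, trace the estimate along nested
  top-$k$ sets, and keep the smallest set whose estimate is stable.

## The estimator

All methods feed into the augmented inverse-probability-of-treatment
weighting (AIPTW) estimator
$$
\hat\tau = \frac{1}{n} \sum_{i=1}^n \Big[ (2Z_i - 1)\, \hat W_i
  \big(Y_i - \hat m_{Z_i}(X_i)\big) + \hat m_1(X_i) - \hat m_0(X_i) \Big],
\qquad
\hat W_i = \frac{Z_i}{\hat e_i} + \frac{1 - Z_i}{1 - \hat e_i},
$$
with $\hat m_z$ the outcome-model prediction under arm $z$. The estimator is
consistent if either the propensity model or the outcome model is correct
(double robustness), and data-adaptive selection steps retain valid
inference only in combination with such doubly robust estimators. The
variance is estimated by the sample variance of the per-unit influence
contributions $\hat\psi_i$ divided by $n$, and confidence intervals are
Wald intervals. Two conventions worth stating explicitly:

* fitted propensity scores are clipped to $[10^{-6}, 1 - 10^{-6}]$ before
  inversion, so separation degrades gracefully instead of producing
  infinite weights;
* the outcome model is a single joint OLS of $Y$ on an intercept, $Z$ and
  the adjustment covariates (not two arm-specific fits), so
  $\hat m_1 - \hat m_0$ is the $Z$ coefficient for every unit. The original
  analyses do not state which convention they used; the joint fit is the
  one the OAL construction implies, and arm-specific fits would change
  nothing in noise-free checks but slightly alter finite-sample behaviour.

## The synthetic data-generating process

`scenario_config()` / `simulate_scenario()` reproduce the study design this
package is organised around. $J \in \{20, 40\}$ covariates are multivariate
standard normal with common correlation $\rho \in \{0, 0.5\}$ (generated
through a one-factor representation, which gives the equicorrelation matrix
exactly). Treatment follows a logistic model with coefficients
$(0.5, 0.5, 0, 0, \theta, \theta, 0, \dots)$ and the outcome a linear model
with coefficients $(1, 1, 1, 1, 0, \dots)$ and noise SD 2, so that

* $X_1, X_2$ are true confounders,
* $X_3, X_4$ predict only the outcome,
* $X_5, X_6$ are IVs of strength $\theta \in \{0.5, 1\}$,
* the remaining $J - 6$ covariates are spurious.

The true ATE is 1 under both the homogeneous ($\tau Z$) and heterogeneous
($(1 + X_1 + X_2) Z$, whose mean is 1) effect variants. These defaults are
the study conditions, not tuning knobs. One master seed per dataset drives
three independent sub-streams (covariates, treatment, noise), so a dataset
component can be regenerated in isolation.

The generator emulates the features that matter for the comparison —
overlap deteriorating with $\rho$ and $\theta$ (the fraction of true scores
outside $[0.1, 0.9]$ grows from $\approx 0.03$ at $\rho = 0, \theta = 0.5$
to $\approx 0.37$ at $\rho = 0.5, \theta = 1$), equicorrelated Gaussian
covariates, linear outcome surfaces. It deliberately does not emulate
non-Gaussian covariates, nonlinear outcome surfaces, or binary outcomes, so
simulation results here say nothing about, e.g., model misspecification
robustness on real data beyond what double robustness guarantees.

```{r overlap}
dat <- simulate_scenario(scenario_config(10000, J = 20, rho = 0.5,
                                         theta = 1, seed = 1))
extreme_ps_fraction(true_ps(dat))
```

## Outcome-adaptive lasso

The propensity coefficients maximize the penalized log-likelihood (on the
sum scale)
$$
\sum_i \big[ Z_i(\beta_0 + \beta^\top X_i) - \log(1 + e^{\beta_0 +
\beta^\top X_i}) \big] - \lambda_n \sum_j \hat\omega_j |\beta_j|,
\qquad \hat\omega_j = |\tilde\alpha_j|^{-\gamma},
$$
with $\tilde\alpha$ the covariate coefficients of the full outcome model on
standardized covariates. The candidate penalties are $\lambda_n = n^a$ for
$a \in \{-10, -5, -2, -1, -0.75, -0.5, -0.25, 0.25, 0.49\}$, and for each
$\lambda_n$ the exponent $\gamma$ solves $\lambda_n n^{\gamma/2 - 1} = n^2$
exactly ($\gamma = 2(3 - \log_n \lambda_n)$), which keeps the selection
consistency conditions satisfied along the whole grid. The grid value is
chosen by the weighted absolute mean difference (wAMD): covariate imbalance
between Hájek-weighted group means, weighted by $|\tilde\alpha_j|$, so
imbalance in outcome-irrelevant covariates costs nothing.

Numerical choices:

* the solver is `glmnet`, with the exact objective mapping
  $\tilde\lambda = (\lambda/n) \cdot \sum_j \omega_j / J$ and
  `penalty.factor` $= \omega$ (glmnet rescales penalty factors to sum to
  the number of covariates; the mapping undoes that). The tests verify the
  fit against an independent proximal-gradient solver to $10^{-4}$;
* $\omega_j$ is capped at $10^8$, so a zero outcome coefficient excludes a
  covariate for any non-negligible $\lambda$ rather than producing an
  infinite penalty. A consequence worth knowing: at the extreme small end
  of the grid ($\lambda = n^{-10}$) the product $\lambda \cdot 10^8$ is
  itself negligible, so those fits are effectively unpenalized;
* wAMD ties (within $10^{-10}$) break toward the smaller $\lambda$ — the
  side consistent with the unpenalized fit. With a constant outcome all
  $\tilde\alpha_j$ are exactly zero, every wAMD is zero, and the smallest
  $\lambda$ is returned deterministically;
* $\tilde\alpha$ is computed once from the full outcome model, not
  refreshed per $\lambda$, and wAMD is evaluated on the standardized
  covariates (the scale on which $\tilde\alpha$ lives);
* the final propensity scores use the penalized coefficients directly — no
  unpenalized refit on the selected support — and the outcome model of the
  final AIPTW uses the selected (nonzero) covariates, sharing the
  adjustment set with the propensity model.

```{r oal}
fit_oal <- estimate_oal(dat[1:1000, ])
glance(fit_oal)
fit_oal$selected_set
```

## Stable balancing weights

Per treatment group, SBW solves
$$
\min_{\omega} \sum_{i} (\omega_i - \bar\omega)^2
\quad \text{s.t.} \quad
\Big| \sum_{i} \omega_i B_k(X_i) - \tfrac1n \sum_{i'} B_k(X_{i'}) \Big|
\le \delta_k, \quad \sum_i \omega_i = 1, \quad \omega_i \ge 0,
$$
balancing each group toward the *overall* sample means (the ATE target
population). The balance functions default to the raw covariates;
interactions or squares can be supplied through the `balance` argument. The
tolerances are $\delta_k = \delta \cdot S_k^z$ with $S_k^z$ the unweighted
within-group SD, $\delta$ drawn from
$\{10^{-4}, 0.001, 0.002, 0.005, 0.01, 0.02, 0.05, 0.1\}$ and selected by a
bootstrap: weights are solved once on the original sample; each resample
(units drawn with replacement, carrying their original weights renormalized
within group) yields the summed standardized absolute distances between
weighted group means and the original overall means; the $\delta$ with the
smallest bootstrap average wins, ties toward the smaller $\delta$. The
wording of the published tuning procedure is ambiguous about whether
weights are re-solved on every resample; the carry-forward reading is the
default here and re-solving is available as
`sbw_control(resolve_per_bootstrap = TRUE)`.

Because the weights sum to one inside each group, minimizing their variance
is the same as minimizing $\sum_i \omega_i^2$, a strictly convex quadratic
program with identity Hessian. The package solves it through the program's
smooth concave dual (dimension $2K + 1$ regardless of group size) with
L-BFGS-B, recovering the primal as
$\omega = \max(0, \nu - B(\alpha - \beta))$. This keeps a full tolerance
search at $n = 500$ under 0.2 s. A candidate is declared feasible when the
recovered weights satisfy every constraint within $10^{-6}$; an infeasible
candidate (the target means lie outside what convex combinations of the
group's rows can reach) is skipped, and the tests cross-check the solver
against both an interior-point QP solver and a dense simplex grid search.

For estimation the group weights are rescaled to the IPW scale (multiplied
by $n$) before entering the AIPTW formula, since IPW weights within a group
sum to $n$ in expectation; the outcome model uses the full covariate set.

```{r sbw}
fit_sbw <- estimate_sbw(dat[1:1000, ], sbw_control(n_bootstrap = 50,
                                                   seed = 2))
glance(fit_sbw)
fit_sbw$selected_multiplier
```

## Stable confounder selection

SCS orders covariates by the weaker of their two association strengths —
$\min(|z_j|, |t_j|)$ from the full logistic treatment model and the full
OLS outcome model — so that only dual-association covariates (confounders)
rank high, with ties broken by the larger statistic and then column order.
AIPTW estimates are computed along the nested top-$k$ sets, smoothed by an
inverse-variance-weighted moving average with window width 5, and the
selected set is the smallest $k$ minimizing $|\hat\tau_k - \mathrm{MA}_k|$.
The reported standard error is the naive influence-function SE at the
selected $k$, with no post-selection correction — by design, since the
method's degraded coverage in hard scenarios is part of what the simulation
study measures.

The published description of this method defers its exact stability
equation to an external source, so the criterion here is a documented
stand-in chosen for directness, isolated in `select_stable()` so an
alternative can be swapped in. Two consequences observed in this package's
own simulations (and computed by its tests): the average model-based SE
falls below the empirical SE in the strong-IV correlated scenarios (the
expected direction), but the selected sets tend to be larger than those the
original implementation appears to produce, which moderates the
under-coverage: at $J = 40$, $\rho = 0.5$, $\theta = 1$ this implementation
attains near-nominal coverage where the published figure is well below
nominal. Reproductions of published SCS rows should therefore be read with
that caveat.

```{r scs}
fit_scs <- estimate_scs(dat[1:1000, ])
glance(fit_scs)
fit_scs$selected_k
```

## The Monte Carlo harness

`run_scenario()` replicates a scenario (replicate $r$ re-seeds the
generator at `base_seed + r`, so all methods see identical data within a
replicate and any replicate is re-runnable in isolation) and
`summarize_performance()` computes, per method: absolute bias, MSE,
relative MSE against the `Target` benchmark (the AIPTW estimator adjusting
for the ideal set $X_1\ldots X_4$), empirical SD of the estimates, average
model-based SE, and 95% coverage — each with a Monte Carlo standard error.
`Confounders` ($X_1\ldots X_6$, i.e. including the IVs) and
`AllCovariates` complete the fixed variants; per-method failures are
counted and excluded rather than imputed. `run_grid()` crosses the full
design ($n \in \{500, 2000\}$, $J$, $\rho$, $\theta$, effect type — 32
scenarios) and writes per-scenario CSV tables.

Problem sizes used by this package's own checks: the benchmark and
all-covariates reproductions run the full 500 replicates; SBW reproductions
run 150–200 replicates with 50 bootstrap resamples; SCS runs 200
replicates. These scales keep the whole verification suite within a few
minutes while leaving Monte Carlo error well inside the comparison
tolerances (e.g. an R-MSE ratio at 200 paired replicates carries an MC SE
of roughly 0.05).

```{r harness, eval = FALSE}
est <- run_scenario(scenario_config(500, J = 20, rho = 0.5, theta = 0.5,
                                    seed = 1),
                    n_reps = 200, methods = c("Target", "SBW"),
                    sbw_control = sbw_control(n_bootstrap = 50))
summarize_performance(est)
```

## Diagnostics

`weighting_diagnostics()` reports the effective sample size
$(\sum w)^2 / \sum w^2$ and the maximum normalized weight ($\times 100$)
per group, plus population standardized differences
$|\bar X_{j}^{w,z} - \bar X_j| / S_j^z$ per covariate and group, against
the conventional 0.1 adequacy line. ESS is invariant to weight rescaling,
so it does not matter whether IPW-scale or group-normalized weights are
passed.

## Known limitations

* The SCS stability criterion is a stand-in (see above); its reproduction
  quality is scenario-dependent.
* The dual QP solver assumes the identity-Hessian structure of this
  particular balancing program; it is not a general-purpose QP interface.
* Binary outcomes are not simulated; the estimator plumbing accepts any
  outcome-model predictions, but the acceptance surface is the continuous
  outcome design.
* No selection-aware inference corrections anywhere — intentionally, since
  naive post-selection SEs are part of what is being compared.
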