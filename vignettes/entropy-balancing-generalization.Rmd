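---
title: "Generalizing treatment effects to a summary-level target: models, solvers and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalizing treatment effects to a summary-level target}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebtransport)
```

## The problem

A treatment effect estimated in one population (a trial site, a surgical
ICU, a study cohort) rarely transfers unchanged to another: when the
individual effect $\tau(x) = \mu_1(x) - \mu_0(x)$ depends on covariates
("effect modifiers") and the covariate distribution shifts between
populations, the average treatment effect (ATE) shifts too. `ebtransport`
estimates the **target-population ATE**

$$\tau^* = E\{Y(1) - Y(0) \mid S = 0\}$$

($S = 1$ marks membership in the source sample, $S = 0$ the target) under a
deliberately asymmetric data regime: individual-level covariates, treatment
and outcome for the $n_s$ source subjects, but only **moment summaries**
from the $n_t$ target subjects — the averages $\bar h_{k,\mathcal T}$ of a
set of covariate functions $h_k$, plus the sampling variances of those
averages. This is the situation when a collaborating site can release
published-table-style summaries but not records.

## Identification and the balancing weights

Under the usual assumptions (SUTVA; no unmeasured confounding of treatment
in the source; positivity of both the propensity $\pi(x) = P(A=1 \mid x,
S=1)$ and the participation probability $\rho(x) = P(S=1 \mid x)$; mean
exchangeability of potential outcomes across populations), $\tau^*$ is
identified by a weighted contrast of source outcomes,

$$\hat\tau_w = \frac{1}{n_s}\sum_{i \in \mathcal S_1} w_i Y_i -
  \frac{1}{n_s}\sum_{i \in \mathcal S_0} w_i Y_i,$$

with population weights built from $\pi$, $\rho$ and $E(S)$. Estimating
those nuisance functions directly is unstable and, for $\rho$, impossible
without target individual data. Entropy balancing sidesteps both: choose
the weights minimizing $\sum_i w_i \log w_i$ subject to

* each arm's weighted $h_k$-moments equal the target's reported
  $\bar h_{k,\mathcal T}$ (covariate-shift adjustment, the $H$ set),
* the two arms' weighted $g_k$-moments agree with each other (residual
  confounding adjustment, the $G$ set),
* each arm's weights average to one ($\tfrac{1}{n_s}\sum_{\text{arm}} w_i
  = 1$ — note each arm's weights sum to $n_s$, not to 1; other conventions
  exist in the weighting literature).

The normalization rides along as the constant moment $h_0 \equiv 1$. The
weighting estimator is consistent when either (a) both conditional outcome
means are linear in $H$, or (b) the treatment log-odds lies in
span$\{H, G\}$ and $\tau(x)$ in span$\{H\}$ — the two "consistency
conditions" that organise the simulation designs below.

### The dual and the solver

The constrained problem is solved through its unconstrained strictly
convex dual: with $w_i = \exp\{\lambda_1^\top H(X_i) + \gamma^\top
G(X_i)\}$ on the treated and $\exp\{\lambda_0^\top H(X_i) - \gamma^\top
G(X_i)\}$ on controls, minimize

$$f(\lambda_1, \lambda_0, \gamma) = \frac{1}{n_s}\sum_{\mathcal S_1}
e^{\lambda_1^\top H + \gamma^\top G} + \frac{1}{n_s}\sum_{\mathcal S_0}
e^{\lambda_0^\top H - \gamma^\top G} - (\lambda_1 + \lambda_0)^\top
\bar H_{\mathcal T}.$$

The gradient entries are exactly the balance residuals, so the convergence
tolerance on the gradient max-norm (default $10^{-8}$) is also a residual
guarantee. Numerical choices, all configurable via `eb_options()`:

* **Damped Newton with the analytic Hessian** $(1/n_s) Z^\top
  \mathrm{diag}(w) Z$ and Armijo backtracking, implemented in compiled
  code because the resampling studies call it hundreds of thousands of
  times. A ridge rescue and a gradient-direction fallback cover
  near-singular Hessians; a stagnation test (several consecutive
  machine-precision objective decreases with the gradient below $10^{-6}$)
  stops the iteration when the optimum is reached to floating-point
  accuracy but the $10^{-8}$ target sits below the attainable noise floor.
* **Centering.** Non-constant $H$/$G$ columns are centered at their source
  means (targets shifted identically) before solving, which conditions the
  exponentials; only the intercept coordinates change, and the solution is
  translated back, so centering is a pure reparametrization (tested).
* **Infeasibility certificate.** The primal has no solution exactly when
  the target moments leave the convex hull of the (resampled) source
  moments, i.e., when the dual is unbounded below. We declare
  infeasibility when the parameter max-norm exceeds 100 (centered scale)
  with the gradient still above $10^{-6}$, or when 500 iterations pass
  without convergence. After centering, multipliers of solvable instances
  sit orders of magnitude below the bound, so the classification measures
  the hull geometry rather than the thresholds; both are configurable.

### Approximate balance

In small or noisy samples the exact constraints may be unsatisfiable.
Relaxing each moment constraint to $|\text{weighted moment} - \text{target}|
\le \delta$ adds L1 penalties $|\lambda_1|^\top\delta_1 +
|\lambda_0|^\top\delta_1' + |\gamma|^\top\delta_2$ to the dual. We solve
the nonsmooth problem by splitting each penalized coordinate into positive
and negative parts, a smooth bound-constrained program handled by
projected quasi-Newton (L-BFGS-B); the constant-moment slacks are pinned
to zero so per-arm normalization stays exact. Complementary slackness
(active slacks bind, inactive multipliers vanish) and agreement with an
independent general-purpose solver are tested.

How much slack? Two rules are provided, because the degree-selection
procedure is stated only loosely in the source methodology:

* `proportional` (default): $\delta = \text{fraction} \times
  |\hat\lambda|$ from the exact solve on the original data — constraints
  with strong multipliers are the expensive ones, and relaxing them
  restores feasibility cheapest;
* `inverse`: adaptive-LASSO-style $\delta \propto
  \text{fraction}/|\hat\lambda|$ with a cap for near-zero coefficients.

The escalation schedule of fractions (0.05, 0.1, 0.2, 0.4, 0.8) is a
geometric grid stopping at first convergence; it is configurable. When
even the largest fraction fails — which happens precisely when a needed
moment's original-data multiplier is near zero, so the proportional rule
never relaxes it — the engine escalates through the standard-deviation
heuristic instead: slacks of $0.1 \times$ each moment's SD, doubling until
a solution exists. The SD heuristic is also the fallback when the
*original* (unperturbed) problem is infeasible, where no exact dual exists
to take fractions of.

## Interval construction by resampling-based perturbation

The asymptotic variance of $\hat\tau_w$ involves target individual data,
so a plug-in CI is unavailable by construction. Instead, each replicate
$b = 1, \dots, B$ perturbs both inputs:

1. **Source:** a nonparametric bootstrap of the $n_s$ subjects, drawn from
   the pooled sample (not stratified by arm — the procedure resamples "the
   source population"; replicates with an empty arm are redrawn).
2. **Target:** a parametric Gaussian draw $\bar H_{\mathcal T}^{(b)} \sim
   N(\bar H_{\mathcal T}, D^{1/2}\hat R D^{1/2})$, where $D$ holds the
   reported variances of the target *means* and $\hat R$ is the
   correlation of the $H$ columns in the source, both arms pooled —
   summary tables rarely report cross-moment covariances, so the
   correlation is borrowed from the source (a user-supplied full
   covariance takes precedence). Binary moments may omit the variance;
   it is filled as $\bar h(1-\bar h)/n_t$.

Weights and $\hat\tau_w^{(b)}$ are recomputed per replicate and the 95% CI
is the empirical 2.5/97.5 percentile interval (linear interpolation
between order statistics, the `quantile()` default). Two variants:

* **RPM-CI** solves each replicate exactly; infeasible replicates are
  dropped and counted. The reported infeasibility share counts
  perturbation replicates only, not the original solve.
* **RPM-AB** rescues infeasible replicates through the relaxation
  escalation above, so every replicate contributes. Its intervals are
  wider and its coverage better exactly when infeasibility is common.

Reproducibility: the master seed spawns an independent substream per
replicate, so results are independent of execution order and identical
across runs; paired RPM-CI/RPM-AB runs under one seed share every draw,
differing only on rescued replicates.

## The synthetic-data engine

The generator emulates a two-population observational study: five
covariates uniform on an interval (independent, or equicorrelated through
a Gaussian copula — the latent correlation $2\sin(\pi\rho_u/6)$ makes the
uniforms' Pearson correlation exactly the design value); participation
$S \sim \text{Bern}(\rho(X))$ splitting the population; treatment
$A \sim \text{Bern}(\pi(X))$ in the source; outcomes $Y = m(X) +
(A - 0.5)\tau(X) + \varepsilon$, $\varepsilon \sim N(0,1)$. The formula
registry enumerates linear and nonlinear $\pi$ and $\rho$, three CATE
shapes (linear in $H$; loading on the $G$ covariates; exponential in $H$)
and three main effects, so every combination of consistency condition
(a)/(b)/none is constructible; `design_preset()` names the full evaluation
grid. The default conditions are the study settings: $n = 800$ with
$X \sim U(-2,2)$ (always-feasible regime), and the small-sample noisy
regime $n = 400$, $X \sim U(-2,6)$ where infeasible replicates are common.
Target summaries carry the exact target-side moment means with
variance-of-the-mean entries, i.e., what a cooperating site would report.

What the generator does *not* emulate: real covariate structure (mixed
discrete/continuous, skewness, missingness), outcome heteroscedasticity
($\sigma_a(x)$ is the constant 1 here), or cluster structure. Passing
tests therefore demonstrate correctness of the machinery and calibration
under the stated designs, not robustness to arbitrary real data.

## Worked example

```{r example}
set.seed(1)
design <- design_preset("table1_linear_T1M2")
study <- generate_study(design)
spec <- default_balance_spec()

sol <- solve_exact(evaluate_spec(study$source, spec),
                   study$target_summary)
sol
weighted_ate(sol$weights, study$source)

ci <- rpm_ci(study$source, study$target_summary, spec, B = 300, seed = 7)
ci
true_target_ate(design, n_mc = 1e5)$estimate
```

A full evaluation row — `M` studies, coverage of the truth, averaged
endpoints — comes from `run_design()`:

```{r run-design, eval = FALSE}
run_design(design_preset("table3_linear_T1M2"), "rpm-ab",
           M = 100, B = 200, seed = 1)
```

## Problem sizes and open choices

The package's own reproduction studies run at $M = 200$ simulated studies
with $B = 300$ perturbation replicates (Table-1/2-style designs) and
$M = 100$–$150$ with $B = 200$ (small-sample designs), with the binomial
Monte-Carlo error these sizes imply (about $\pm 1.5$–3 coverage points);
`--full-scale` in the CLI runs $M = 500$, $B = 1000$. Choices that were
genuinely open and how they were settled:

* *Feasible-only percentiles for RPM-CI.* Infeasibility rates are reported
  alongside coverage, which implies the interval is formed from the
  feasible replicates; we drop-and-count and document it.
* *Moment naming.* Source columns and target summaries are matched by
  moment name, so file orderings never matter.
* *Averaged CI columns.* Study-level "average (CI)" cells average the
  point estimates and the two endpoints across the $M$ studies.
* *Effective sample sizes* per arm are reported as a diagnostic (extreme
  weights explain wide intervals); they are plumbing, not part of the
  method.
* *Near-infeasible solutions.* When the dual converges but some weight is
  enormous, the solution is returned with `max_weight` as the diagnostic;
  thresholding is left to the user.

Known limitations: no doubly-robust augmentation; no alternative
divergences (entropy only); no individual-level target ingestion (the
method's premise is its absence); inference assumes the target summary's
variances are correct as reported.
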