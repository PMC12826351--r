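# ebtransport

Entropy-balancing generalization of treatment effects to a target
population described only by summary statistics, with resampling-based
confidence intervals.

## The problem

Biomedical effect estimates rarely transfer unchanged between populations:
when individual treatment effects depend on covariates and those
covariates shift between a source (a trial, a surgical ICU, a registry)
and a target population, the average treatment effect (ATE) shifts too.
`ebtransport` is for the common asymmetric data situation: you hold
individual-level covariates, treatment and outcomes for the source, but
the target is known only through *moment summaries* — published-table
means $\bar h_{k,\mathcal T}$ of covariate functions, their sampling
variances, and the target sample size. The target estimand is

$$\tau^* \;=\; E\{Y(1) - Y(0)\mid S = 0\},$$

the ATE in the target population ($S=0$).

## The method

**Weights.** Calibration weights for the source subjects minimize the
entropy $\sum_i w_i \log w_i$ subject to (i) each treatment arm's weighted
$H$-moments matching the target's reported values (covariate-shift
adjustment), (ii) the arms' weighted $G$-moments matching each other
(confounding adjustment), and (iii) each arm's weights averaging to one.
The problem is solved through its strictly convex unconstrained dual,
$w_i = \exp\{\lambda_1^\top H(X_i) + \gamma^\top G(X_i)\}$ on the treated
arm and $\exp\{\lambda_0^\top H(X_i) - \gamma^\top G(X_i)\}$ on controls,
by damped Newton with analytic Hessian (compiled code). A diverging dual
certifies that the target moments lie outside the convex hull of the
source moments — the problem is infeasible. The weighted contrast
$\hat\tau_w = \tfrac1{n_s}\sum_{S_1} w_i Y_i - \tfrac1{n_s}\sum_{S_0}
w_i Y_i$ estimates $\tau^*$.

**Approximate balance.** When exact matching is infeasible, each
constraint relaxes to $|\text{weighted moment} - \text{target}| \le
\delta$; the dual gains L1 penalties $|\lambda_1|^\top\delta_1 +
|\lambda_0|^\top\delta_1' + |\gamma|^\top\delta_2$ and is solved by an
orthant-wise Newton method. Slack magnitudes default to fractions of the
exact-balancing dual coefficients, escalating until a solution exists,
with a 0.1-SD-per-moment fallback.

**Intervals (RPM-CI / RPM-AB).** Because the estimator's asymptotic
variance involves unavailable target individual data, intervals come from
resampling-based perturbation: each of B replicates combines a
nonparametric bootstrap of the source with a Gaussian draw of the target
moment vector ($N(\bar H_{\mathcal T}, D^{1/2}\hat R D^{1/2})$, variances
$D$ as reported, correlation $\hat R$ borrowed from the source), re-solves
the weights and re-estimates; the 2.5/97.5 percentiles of the replicate
estimates form the 95% CI. RPM-CI drops and counts infeasible replicates;
RPM-AB rescues them by approximate balancing.

A synthetic-data engine (`simulation_design()`, `generate_study()`,
`design_preset()`) and a study driver (`run_design()`) reproduce
bias/coverage/infeasibility evaluations over the enumerated design grid.

## Worked example

```r
library(ebtransport)
set.seed(1)

design <- design_preset("table1_linear_T1M2")  # n = 800, X ~ U(-2,2)^5
study  <- generate_study(design)               # source data + target summary
spec   <- default_balance_spec()               # H = (1, x1, x2, x3); G = (x4, x5)

sol <- solve_exact(evaluate_spec(study$source, spec), study$target_summary)
sol
#> <balancing_solution> status: converged (gradient max-norm 2.22e-15, 5 iterations)
#>   weights: n = 404, max = 9.98; max |residual| = 2.22e-15

weighted_ate(sol$weights, study$source)
#> <ate_estimate> tau_hat = -0.2631 (treated -0.2256 - control 0.0375); ESS 102.1 / 151.6

ci <- rpm_ci(study$source, study$target_summary, spec, B = 300, seed = 7)
ci
#> <RPM-CI> tau_hat = -0.2631, 95% CI (-0.5793, 0.0510)
#>   B = 300 requested, 300 used; infeasible/rescued: 0

true_target_ate(design, n_mc = 1e5)$estimate
#> [1] -0.144342
```

Reading: the balancing solve converged with residuals at machine
precision; the weighted contrast estimates the target ATE at −0.263 with
95% perturbation interval (−0.579, 0.051), which covers the
Monte-Carlo truth ≈ −0.144 for this design. `ESS` is the effective
sample size per arm after weighting. On file-based inputs the same
pipeline is `read_source()` → `read_target_summary()` →
`spec_from_target()` → `solve_exact()` → `rpm_ci()`/`rpm_ab_ci()` →
`write_results()`, or the CLI at `inst/cli/ebtransport.R`
(`estimate`, `ci`, `simulate` subcommands).

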