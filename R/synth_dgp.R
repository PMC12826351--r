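# Synthetic study generator: a five-covariate population split into a
# source (individual data observed) and a target (moment summaries only) by
# a participation model, with a confounded binary treatment and an
# effect-modified continuous outcome. The formula registry enumerates the
# propensity, participation, treatment-effect and main-effect models of the
# evaluation designs.

cate_registry <- list(
  T1 = function(X) X[, 1L] - 0.6 * X[, 2L] - 0.4 * X[, 3L],
  T2 = function(X) X[, 1L] - 0.6 * X[, 2L] - 0.4 * X[, 3L] +
    0.8 * X[, 4L] - 0.3 * X[, 5L],
  T3 = function(X) X[, 1L] - 0.5 * exp(X[, 2L] - 0.8 * X[, 3L]))

main_registry <- list(
  M1 = function(X) 0.5 * X[, 1L] + 0.3 * X[, 2L] + 0.3 * X[, 3L],
  M2 = function(X) 0.5 * X[, 1L] + 0.3 * X[, 2L] + 0.3 * X[, 3L] -
    0.4 * X[, 4L] - 0.7 * X[, 5L],
  M3 = function(X) 0.5 * X[, 1L] + 0.8 * X[, 2L]^2 +
    0.2 * exp(0.5 * X[, 3L] - X[, 4L] - 1) - 0.7 * X[, 5L])

propensity_registry <- list(
  linear = function(X) plogis(0.7 * X[, 2L] + 0.5 * X[, 3L]),
  nonlinear = function(X) plogis(0.35 * X[, 2L] -
    0.4 * pmax(X[, 3L], X[, 4L]) - 0.7 * X[, 5L]))

participation_registry <- list(
  linear = function(X) plogis(0.4 * X[, 1L] + 0.3 * X[, 2L] -
    0.2 * X[, 4L]),
  nonlinear = function(X) plogis(0.3 * X[, 1L] +
    0.5 * X[, 2L] * X[, 4L] - 0.2 * X[, 4L]))

#' Define a simulation design
#'
#' Five covariates are drawn from a (possibly equicorrelated) uniform
#' distribution; a participation model splits subjects into source and
#' target; treated/control status in the source follows a propensity model;
#' outcomes follow `Y = m(X) + (A - 0.5) tau(X) + eps`, `eps ~ N(0, 1)` (so
#' the conditional outcome SD is the constant 1 and the conditional
#' treatment effect is exactly `tau`). Formula choices come from the
#' enumerated registries; custom functions may be supplied directly.
#'
#' The default H/G split balances first moments of x1..x3 against the
#' target and x4, x5 across arms. Under the linear propensity its log-odds
#' lies in span(H), so the CATE `T1` (linear in H) satisfies consistency
#' condition (b); under `T1` + `M1` both conditional outcome means are
#' linear in H, satisfying condition (a); otherwise the weighting estimator
#' is not guaranteed consistent ("none").
#'
#' @param n_total total population size (source + target).
#' @param support covariate support, `c(low, high)`.
#' @param correlation pairwise Pearson correlation of the covariates
#'   (Gaussian copula, in `[0, 1)`).
#' @param propensity `"linear"`, `"nonlinear"`, or a function of the
#'   covariate matrix returning treatment probabilities.
#' @param participation `"linear"`, `"nonlinear"`, or a function returning
#'   source-membership probabilities.
#' @param cate `"T1"`, `"T2"`, `"T3"`, or a function.
#' @param main_effect `"M1"`, `"M2"`, `"M3"`, or a function.
#' @param id optional design label.
#' @return A `simulation_design` with the resolved functions, the formula
#'   labels, and the consistency condition (`"(a)"`, `"(b)"` or `"none"`)
#'   when all formulas come from the registry.
#' @export
simulation_design <- function(n_total = 800L, support = c(-2, 2),
                              correlation = 0,
                              propensity = c("linear", "nonlinear"),
                              participation = c("linear", "nonlinear"),
                              cate = c("T1", "T2", "T3"),
                              main_effect = c("M1", "M2", "M3"),
                              id = NULL) {
  resolve <- function(x, registry, label) {
    if (is.function(x)) return(list(fn = x, name = "custom"))
    x <- match.arg(x, names(registry))
    list(fn = registry[[x]], name = x)
  }
  pr <- resolve(propensity, propensity_registry)
  pa <- resolve(participation, participation_registry)
  ct <- resolve(cate, cate_registry)
  mn <- resolve(main_effect, main_registry)
  if (support[1L] >= support[2L]) stop("support must satisfy low < high")
  if (correlation < 0 || correlation >= 1) {
    stop("correlation must lie in [0, 1)")
  }
  condition <- if (ct$name == "custom" || pr$name == "custom") {
    NA_character_
  } else if (pr$name == "linear" && ct$name == "T1") {
    "(b)"
  } else if (ct$name == "T1" && mn$name == "M1") {
    "(a)"
  } else {
    "none"
  }
  if (is.null(id)) {
    id <- sprintf("%s_%s%s_n%d", pr$name, ct$name, mn$name, n_total)
  }
  structure(list(n_total = as.integer(n_total), p = 5L,
                 support = support, correlation = correlation,
                 pi_fun = pr$fn, rho_fun = pa$fn,
                 tau_fun = ct$fn, m_fun = mn$fn,
                 propensity = pr$name, participation = pa$name,
                 cate = ct$name, main_effect = mn$name,
                 condition = condition, id = id),
            class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf("<simulation_design> %s: n = %d, X ~ U(%g, %g)^5 (corr %g)\n",
              x$id, x$n_total, x$support[1L], x$support[2L], x$correlation))
  cat(sprintf("  propensity %s, participation %s, CATE %s, main effect %s; consistency condition: %s\n",
              x$propensity, x$participation, x$cate, x$main_effect,
              x$condition))
  invisible(x)
}

#' Draw covariates under a design
#'
#' Independent case: i.i.d. uniform on the support. Correlated case:
#' equicorrelated Gaussian copula mapped through the normal CDF to uniform
#' marginals; the latent correlation `r = 2 sin(pi rho_u / 6)` makes the
#' Pearson correlation of the resulting uniforms exactly the design value.
#'
#' @param design a [simulation_design()].
#' @param n number of draws.
#' @return An `n` x 5 matrix with columns `x1..x5`, all values inside the
#'   support.
#' @export
sample_covariates <- function(design, n) {
  stopifnot(n >= 1L)
  p <- design$p
  if (design$correlation == 0) {
    U <- matrix(runif(n * p), n, p)
  } else {
    r <- 2 * sin(pi * design$correlation / 6)
    Zl <- sqrt(r) * rnorm(n) + sqrt(1 - r) * matrix(rnorm(n * p), n, p)
    U <- pnorm(Zl)
  }
  X <- design$support[1L] + diff(design$support) * U
  colnames(X) <- paste0("x", seq_len(p))
  X
}

#' Default balance specification for the simulated studies
#'
#' H balances the first moments of `x1`, `x2`, `x3` (the covariates whose
#' target summaries are reported) plus the constant; G equalizes `x4`, `x5`
#' across source arms.
#' @return A [balance_spec()].
#' @export
default_balance_spec <- function() {
  balance_spec(h = c("x1", "x2", "x3"), g = c("x4", "x5"))
}

#' Generate one study (source sample + target summary) under a design
#'
#' Each subject draws covariates, a population indicator
#' `S ~ Bernoulli(rho(X))` (S = 1 means source), and — for source subjects —
#' treatment `A ~ Bernoulli(pi(X))` and the outcome. The target summary
#' holds the spec's H moments averaged over the target rows exactly, with
#' variance-of-the-mean entries (column variance / n_t), which is what a
#' collaborating target site would report. Target individual data are
#' retained for validation only and never enter estimation.
#'
#' @param design a [simulation_design()].
#' @param spec a [balance_spec()] whose H moments define the reported
#'   summaries (default [default_balance_spec()]).
#' @return A `generated_study`: `source` ([source_sample()]),
#'   `target_summary` ([target_summary()]), `target_individual` (matrix),
#'   `S` (population indicator over all `n_total` subjects), `design`.
#' @export
generate_study <- function(design, spec = default_balance_spec()) {
  repeat {
    X <- sample_covariates(design, design$n_total)
    S <- rbinom(design$n_total, 1L, design$rho_fun(X))
    src <- S == 1L
    n_s <- sum(src); n_t <- design$n_total - n_s
    if (n_s < 2L || n_t < 2L) next  # vanishingly rare at the stated sizes
    Xs <- X[src, , drop = FALSE]
    A <- rbinom(n_s, 1L, design$pi_fun(Xs))
    if (!any(A == 1L) || !any(A == 0L)) next
    Y <- design$m_fun(Xs) + (A - 0.5) * design$tau_fun(Xs) + rnorm(n_s)
    Xt <- X[!src, , drop = FALSE]
    vals <- vars <- numeric(spec$K_h)
    for (k in seq_len(spec$K_h)) {
      col <- eval_moment(spec$h[[k]], Xt)
      vals[k] <- mean(col)
      vars[k] <- var(col) / n_t
    }
    names(vals) <- names(vars) <- spec$h_names
    return(structure(list(
      source = source_sample(Xs, A, Y),
      target_summary = target_summary(vals, vars, n_t = n_t),
      target_individual = Xt,
      S = S, design = design, spec = spec),
      class = "generated_study"))
  }
}

#' Monte-Carlo truth for the target-population ATE
#'
#' `tau* = E[Y(1) - Y(0) | S = 0] = E[tau(X) (1 - rho(X))] / E[1 - rho(X)]`
#' estimated from `n_mc` covariate draws, with the standard error of the
#' ratio estimate.
#'
#' @param design a [simulation_design()].
#' @param n_mc Monte-Carlo size (at least 1e4).
#' @return List with `estimate` and `se`.
#' @export
true_target_ate <- function(design, n_mc = 1e6) {
  stopifnot(n_mc >= 1e4)
  X <- sample_covariates(design, n_mc)
  u <- 1 - design$rho_fun(X)
  tau <- design$tau_fun(X)
  est <- sum(tau * u) / sum(u)
  # delta-method SE of the ratio of means
  infl <- (tau - est) * u / mean(u)
  list(estimate = est, se = sd(infl) / sqrt(n_mc))
}

#' Expected source-membership probability under a design
#' @param design a [simulation_design()].
#' @param n_mc Monte-Carlo size.
#' @return Scalar `E(S)` estimate.
#' @export
expected_source_share <- function(design, n_mc = 1e6) {
  mean(design$rho_fun(sample_covariates(design, n_mc)))
}

#' Identification (oracle) weights
#'
#' The population weight that identifies the target ATE from source data:
#' `w = [a / pi(x) + (1 - a) / (1 - pi(x))] *
#'      E(S) (1 - rho(x)) / [(1 - E(S)) rho(x)]`.
#' Used as a testing oracle: the weighted ATE with these weights recovers
#' `tau*` in large samples.
#'
#' @param design a [simulation_design()].
#' @param x covariate matrix (rows of source subjects).
#' @param a treatment indicator vector.
#' @param ES expected source share; computed by Monte-Carlo
#'   (`n_mc` draws) when omitted.
#' @param n_mc Monte-Carlo size for `ES`.
#' @return Weight vector.
#' @export
oracle_weights <- function(design, x, a, ES = NULL, n_mc = 1e6) {
  x <- matrix(as.numeric(x), ncol = design$p)
  pi_x <- design$pi_fun(x)
  rho_x <- design$rho_fun(x)
  if (any(pi_x <= 0 | pi_x >= 1)) {
    stop("propensity at 0 or 1: positivity of treatment assignment violated")
  }
  if (any(rho_x <= 0 | rho_x >= 1)) {
    stop("participation probability at 0 or 1: positivity violated")
  }
  if (is.null(ES)) ES <- expected_source_share(design, n_mc)
  (a / pi_x + (1 - a) / (1 - pi_x)) *
    ES * (1 - rho_x) / ((1 - ES) * rho_x)
}

#' Named design presets for the simulation studies
#'
#' `table1_*`: n = 800, X ~ U(-2, 2), independent covariates. `table2_*`:
#' the same with pairwise covariate correlation 0.1 or 0.3. `table3_*`:
#' the small-sample noisy setting, n = 400, X ~ U(-2, 6).
#'
#' @param name e.g., `"table1_linear_T1M2"`, `"table2_linear_T1M2_corr01"`,
#'   `"table3_nonlinear_T1M1"`.
#' @return A [simulation_design()].
#' @export
design_preset <- function(name) {
  m <- regmatches(name, regexec(
    "^(table[123])_(linear|nonlinear)_(T[123])(M[123])(?:_corr(01|03))?$",
    name))[[1L]]
  if (!length(m)) stop("unknown design preset: ", name)
  corr <- if (m[6L] == "") 0 else if (m[6L] == "01") 0.1 else 0.3
  if (m[2L] == "table2" && corr == 0) {
    stop("table2 presets need a _corr01 or _corr03 suffix")
  }
  simulation_design(
    n_total = if (m[2L] == "table3") 400L else 800L,
    support = if (m[2L] == "table3") c(-2, 6) else c(-2, 2),
    correlation = corr,
    propensity = m[3L], participation = m[3L],
    cate = m[4L], main_effect = m[5L],
    id = name)
}

#' Read a simulation design from a YAML file
#'
#' Keys: `n_total`, `support` (two numbers), `correlation`, `propensity`,
#' `participation`, `cate`, `main_effect`, optional `id`; or a single
#' `preset` key naming a [design_preset()].
#'
#' @param path YAML file path.
#' @return A [simulation_design()].
#' @export
read_design <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!is.null(obj$preset)) return(design_preset(obj$preset))
  simulation_design(
    n_total = obj$n_total %||% 800L,
    support = as.numeric(obj$support %||% c(-2, 2)),
    correlation = obj$correlation %||% 0,
    propensity = obj$propensity %||% "linear",
    participation = obj$participation %||% "linear",
    cate = obj$cate %||% "T1",
    main_effect = obj$main_effect %||% "M2",
    id = obj$id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
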