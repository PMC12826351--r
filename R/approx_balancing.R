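#' Construct a relaxation specification
#'
#' Slack magnitudes for the relaxed balancing problem: each exact moment
#' constraint `= target` becomes `|weighted moment - target| <= delta`. The
#' entries for the constant moment are forced to 0 so per-arm weight
#' normalization stays exact.
#'
#' @param delta1 nonnegative vector, treated-arm H slacks (length K_h + 1,
#'   constant entry first; a length-K_h vector is padded with the 0 constant
#'   entry).
#' @param delta1_prime control-arm H slacks, same layout.
#' @param delta2 nonnegative vector of G slacks (length K_g).
#' @return A `relaxation_spec`.
#' @export
relaxation_spec <- function(delta1, delta1_prime = delta1,
                            delta2 = numeric(0)) {
  fix <- function(d) {
    d <- as.numeric(d)
    if (any(!is.finite(d)) || any(d < 0)) {
      stop("relaxations must be finite and nonnegative")
    }
    d
  }
  delta1 <- fix(delta1); delta1_prime <- fix(delta1_prime)
  delta2 <- fix(delta2)
  structure(list(delta1 = delta1, delta1_prime = delta1_prime,
                 delta2 = delta2),
            class = "relaxation_spec")
}

# Pad/validate a relaxation against design dimensions; constant entry 0.
conform_relaxation <- function(relaxation, p, q) {
  pad <- function(d, len, label) {
    if (length(d) == len - 1L) d <- c(0, d)
    if (length(d) != len) {
      stop(sprintf("relaxation %s has length %d, expected %d",
                   label, length(d), len))
    }
    d[1L] <- 0
    d
  }
  list(delta1 = pad(relaxation$delta1, p, "delta1"),
       delta1_prime = pad(relaxation$delta1_prime, p, "delta1_prime"),
       delta2 = {
         d <- relaxation$delta2
         if (length(d) != q) stop("relaxation delta2 has wrong length")
         d
       })
}

# Low-level L1-penalized dual solve: orthant-wise damped Newton with the
# exact smooth Hessian (compiled), the nonsmooth analogue of the exact
# solver. Centering is the same pure reparametrization as in eb_core; the
# penalty is unaffected because only intercept coordinates change and
# their slacks are pinned to zero.
eb_approx_core <- function(H, G, A, hbar, delta, options = eb_options()) {
  p <- ncol(H); q <- ncol(G)
  if (options$center && p > 1L) {
    mH <- colMeans(H[, -1L, drop = FALSE])
    Hc <- H; Hc[, -1L] <- sweep(H[, -1L, drop = FALSE], 2L, mH)
    hb <- hbar; hb[-1L] <- hbar[-1L] - mH
  } else { mH <- numeric(p - 1L); Hc <- H; hb <- hbar }
  if (options$center && q > 0L) {
    mG <- colMeans(G); Gc <- sweep(G, 2L, mG)
  } else { mG <- numeric(q); Gc <- G }
  Z <- build_dual_design(Hc, Gc, A)
  cvec <- c(hb, hb, rep(0, q))
  fit <- .eb_orthant_cpp(Z, cvec, delta, options$tol, options$max_iter,
                         options$divergence_bound, options$infeasible_grad)
  list(theta = fit$theta,
       weights = as.numeric(fit$weights),
       value = fit$value,
       smooth_grad = as.numeric(fit$smooth_grad),
       dual = uncenter_dual(fit$theta, p, q, mH, mG),
       status = fit$status,
       iterations = fit$iterations)
}

#' Solve the relaxed (approximate) balancing problem
#'
#' Minimizes the exact balancing dual plus L1 penalties
#' `|lambda1|' delta1 + |lambda0|' delta1' + |gamma|' delta2`, the dual of
#' the balancing problem with inequality (slack) constraints. A converged
#' solution's weights satisfy every relaxed constraint
#' `|weighted moment - target| <= delta` (to tolerance) with exact per-arm
#' normalization. With an all-zero relaxation this is the exact problem and
#' the call is routed to [solve_exact()].
#'
#' @param design a [evaluate_spec()] result.
#' @param summary a [target_summary()].
#' @param relaxation a [relaxation_spec()].
#' @param options an [eb_options()].
#' @return A `balancing_solution` (see [solve_exact()]) with extra fields
#'   `relaxation` (the conformed slacks) and `value` holding the penalized
#'   dual objective.
#' @export
solve_approx <- function(design, summary, relaxation,
                         options = eb_options()) {
  p <- ncol(design$H); q <- ncol(design$G)
  rx <- conform_relaxation(relaxation, p, q)
  if (all(c(rx$delta1, rx$delta1_prime, rx$delta2) == 0)) {
    sol <- solve_exact(design, summary, options)
    sol$relaxation <- rx
    return(sol)
  }
  al <- align_summary(summary, design$spec)
  delta <- c(rx$delta1, rx$delta1_prime, rx$delta2)
  fit <- eb_approx_core(design$H, design$G, design$A, al$values, delta,
                        options)
  dual <- lapply(fit$dual, function(v) {
    names(v) <- if (length(v) == p) colnames(design$H) else colnames(design$G)
    v
  })
  resid <- check_balance(fit$weights, design, summary)
  bounds <- c(rx$delta1, rx$delta1_prime, rx$delta2)
  within <- all(abs(resid$residual) <= bounds + 1e-6)
  status <- if (within) "converged"
            else if (fit$status == 2L) "max_iter"
            else "infeasible"
  structure(list(dual = dual,
                 weights = if (within) fit$weights,
                 status = status,
                 value = fit$value,
                 gradient_norm = max(abs(fit$smooth_grad)),
                 iterations = fit$iterations,
                 balance_residuals = resid,
                 max_weight = if (within) max(fit$weights),
                 relaxation = rx),
            class = "balancing_solution")
}

#' Relaxation magnitudes from the exact dual solution
#'
#' The default rule sets each slack to a fraction of the magnitude of the
#' corresponding exact-balancing dual coordinate,
#' `delta = fraction * |lambda_hat|` (constant entries forced to 0): moments
#' whose constraints bind hard (large multipliers) are relaxed most, which
#' is what restores feasibility cheapest. The `"inverse"` rule is the
#' adaptive-LASSO-style alternative `delta = fraction / |lambda_hat|`,
#' capped for near-zero coefficients, which instead relaxes constraints
#' with weak multipliers.
#'
#' @param exact_dual `dual` element of a converged [solve_exact()] on the
#'   original (unperturbed) data.
#' @param fraction nonnegative scalar.
#' @param rule `"proportional"` (default) or `"inverse"`.
#' @param cap upper bound on each slack under the inverse rule.
#' @return A [relaxation_spec()].
#' @export
select_relaxation <- function(exact_dual, fraction,
                              rule = c("proportional", "inverse"),
                              cap = 10) {
  rule <- match.arg(rule)
  if (!is.finite(fraction) || fraction < 0) {
    stop("fraction must be a nonnegative number")
  }
  f <- switch(rule,
              proportional = function(l) fraction * abs(l),
              inverse = function(l) pmin(fraction / pmax(abs(l), 1e-8), cap))
  d1 <- unname(f(exact_dual$lambda1)); d1[1L] <- 0
  d1p <- unname(f(exact_dual$lambda0)); d1p[1L] <- 0
  d2 <- unname(f(exact_dual$gamma))
  relaxation_spec(d1, d1p, d2)
}

#' Standard-deviation fallback relaxation
#'
#' Slacks set to a constant factor (default 0.1) times the source-sample SD
#' of each moment column — the fallback used when the original exact
#' problem itself has no solution, so there is no exact dual to take
#' fractions of. Escalate by doubling `factor` until a solve converges
#' (see [sd_fallback_solve()]).
#'
#' @param design a [evaluate_spec()] result.
#' @param factor positive slack factor.
#' @return A [relaxation_spec()].
#' @export
sd_fallback_relaxation <- function(design, factor = 0.1) {
  if (!is.finite(factor) || factor <= 0) stop("factor must be positive")
  sdH <- c(0, apply(design$H[, -1L, drop = FALSE], 2L, sd))
  sdG <- if (ncol(design$G)) apply(design$G, 2L, sd) else numeric(0)
  relaxation_spec(factor * sdH, factor * sdH, factor * sdG)
}

#' Solve with the SD fallback, doubling the factor until feasible
#'
#' @inheritParams sd_fallback_relaxation
#' @param summary a [target_summary()].
#' @param options an [eb_options()].
#' @param max_doublings attempts before giving up.
#' @return A converged `balancing_solution` with attribute `"factor"`, or
#'   `NULL` if none of the factors produced a solution.
#' @export
sd_fallback_solve <- function(design, summary, factor = 0.1,
                              options = eb_options(), max_doublings = 10L) {
  for (k in seq_len(max_doublings)) {
    sol <- solve_approx(design, summary,
                        sd_fallback_relaxation(design, factor), options)
    if (sol$status == "converged") {
      attr(sol, "factor") <- factor
      return(sol)
    }
    factor <- 2 * factor
  }
  NULL
}

#' Escalate relaxation fractions until the relaxed solve converges
#'
#' Applies [select_relaxation()] at each fraction of the schedule in turn
#' and returns the first converged [solve_approx()] solution.
#'
#' @param design,summary,options as in [solve_approx()].
#' @param exact_dual dual of the exact solve on the original data.
#' @param fractions increasing relaxation schedule.
#' @param rule passed to [select_relaxation()].
#' @return A converged `balancing_solution` with attribute `"fraction"`, or
#'   `NULL` if no fraction in the schedule worked.
#' @export
solve_with_escalation <- function(design, summary, exact_dual,
                                  fractions = c(0.05, 0.1, 0.2, 0.4, 0.8),
                                  rule = "proportional",
                                  options = eb_options()) {
  for (f in fractions) {
    rx <- select_relaxation(exact_dual, f, rule = rule)
    sol <- solve_approx(design, summary, rx, options)
    if (sol$status == "converged") {
      attr(sol, "fraction") <- f
      return(sol)
    }
  }
  NULL
}
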