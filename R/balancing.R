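#' Solver options for the balancing dual
#'
#' @param tol convergence tolerance on the max-norm of the dual gradient
#'   (the gradient entries are exactly the balance-constraint residuals on
#'   the centered scale, so this is also a residual tolerance).
#' @param max_iter maximum Newton iterations.
#' @param divergence_bound max-norm bound on the (centered) dual parameters
#'   beyond which a still-unconverged solve is declared infeasible; an
#'   unbounded dual is the certificate that the target moments lie outside
#'   the convex hull of the source moments.
#' @param infeasible_grad gradient max-norm above which a diverged parameter
#'   vector is read as infeasibility rather than slow convergence.
#' @param center center non-constant balance columns at their source means
#'   before solving (conditions the exponential terms; the solution is
#'   translated back, so results are unchanged).
#' @return A list of class `eb_options`.
#' @export
eb_options <- function(tol = 1e-8, max_iter = 500L, divergence_bound = 100,
                       infeasible_grad = 1e-6, center = TRUE) {
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 divergence_bound = divergence_bound,
                 infeasible_grad = infeasible_grad,
                 center = isTRUE(center)),
            class = "eb_options")
}

# Stack the subject-level dual design: row [H_i, 0, G_i] for treated,
# [0, H_i, -G_i] for control, in subject order.
build_dual_design <- function(H, G, A) {
  n <- nrow(H); p <- ncol(H); q <- ncol(G)
  Z <- matrix(0, n, 2L * p + q)
  t1 <- A == 1L
  Z[t1, seq_len(p)] <- H[t1, , drop = FALSE]
  Z[!t1, p + seq_len(p)] <- H[!t1, , drop = FALSE]
  if (q) {
    Z[t1, 2L * p + seq_len(q)] <- G[t1, , drop = FALSE]
    Z[!t1, 2L * p + seq_len(q)] <- -G[!t1, , drop = FALSE]
  }
  Z
}

# Centering shifts only the intercept coordinates of the dual; translate a
# centered solution back to the original covariate scale.
uncenter_dual <- function(theta, p, q, mH, mG) {
  l1 <- theta[seq_len(p)]
  l0 <- theta[p + seq_len(p)]
  gm <- if (q) theta[2L * p + seq_len(q)] else numeric(0)
  l1[1L] <- l1[1L] - sum(l1[-1L] * mH) - sum(gm * mG)
  l0[1L] <- l0[1L] - sum(l0[-1L] * mH) + sum(gm * mG)
  list(lambda1 = l1, lambda0 = l0, gamma = gm)
}

# Low-level exact solve on plain matrices (the hot path for resampling).
# H: n x (K_h + 1) with constant first column; G: n x K_g; hbar aligned.
eb_core <- function(H, G, A, hbar, options = eb_options(), start = NULL) {
  p <- ncol(H); q <- ncol(G)
  if (options$center && p > 1L) {
    mH <- colMeans(H[, -1L, drop = FALSE])
    Hc <- H; Hc[, -1L] <- sweep(H[, -1L, drop = FALSE], 2L, mH)
    hb <- hbar; hb[-1L] <- hbar[-1L] - mH
  } else {
    mH <- numeric(p - 1L); Hc <- H; hb <- hbar
  }
  if (options$center && q > 0L) {
    mG <- colMeans(G)
    Gc <- sweep(G, 2L, mG)
  } else {
    mG <- numeric(q); Gc <- G
  }
  Z <- build_dual_design(Hc, Gc, A)
  cvec <- c(hb, hb, rep(0, q))
  if (is.null(start)) start <- rep(0, ncol(Z))
  fit <- .eb_newton_cpp(Z, cvec, options$tol, options$max_iter,
                        options$divergence_bound, options$infeasible_grad,
                        start)
  fit$dual <- uncenter_dual(fit$theta, p, q, mH, mG)
  fit$status_label <- c("converged", "infeasible", "max_iter")[fit$status + 1L]
  fit
}

#' Exact entropy-balancing dual objective and gradient
#'
#' Evaluates the unconstrained dual of the exact balancing problem,
#' `(1/n_s) sum_treated exp(lambda1' H + gamma' G) +
#'  (1/n_s) sum_control exp(lambda0' H - gamma' G) -
#'  (lambda1 + lambda0)' Hbar_T`,
#' and its analytic gradient, whose entries are the balance-constraint
#' residuals (the first-order conditions).
#'
#' @param dual list with `lambda1`, `lambda0` (length K_h + 1) and `gamma`
#'   (length K_g).
#' @param design a [evaluate_spec()] result.
#' @param summary a [target_summary()].
#' @return List with `value` (scalar; `Inf` on exp overflow, with a
#'   `NA` gradient so a line search must backtrack) and `gradient` (stacked
#'   d/d lambda1, d/d lambda0, d/d gamma).
#' @export
dual_objective <- function(dual, design, summary) {
  al <- align_summary(summary, design$spec)
  p <- ncol(design$H); q <- ncol(design$G)
  stopifnot(length(dual$lambda1) == p, length(dual$lambda0) == p,
            length(dual$gamma) == q)
  Z <- build_dual_design(design$H, design$G, design$A)
  theta <- c(dual$lambda1, dual$lambda0, dual$gamma)
  cvec <- c(al$values, al$values, rep(0, q))
  ev <- .eb_dual_eval_cpp(Z, cvec, theta)
  if (!is.finite(ev$value)) {
    return(list(value = Inf, gradient = rep(NA_real_, length(theta))))
  }
  ev
}

#' Weights implied by dual parameters
#'
#' `w_i = exp(lambda1' H(X_i) + gamma' G(X_i))` for treated subjects and
#' `exp(lambda0' H(X_i) - gamma' G(X_i))` for controls, in subject order.
#'
#' @inheritParams dual_objective
#' @return Strictly positive weight vector of length n_s.
#' @export
weights_from_dual <- function(dual, design) {
  Z <- build_dual_design(design$H, design$G, design$A)
  as.numeric(exp(Z %*% c(dual$lambda1, dual$lambda0, dual$gamma)))
}

#' Solve the exact entropy-balancing problem
#'
#' Finds calibration weights minimizing the entropy `sum w log w` subject to
#' matching each source arm's H-moments to the target summary, equalizing
#' G-moments across arms, and normalizing each arm's weights to average 1
#' (`(1/n_s) sum_arm w = 1`, i.e., each arm's weights sum to n_s — note that
#' other conventions, such as weights summing to 1, exist elsewhere). The
#' unconstrained strictly convex dual is minimized by damped Newton with
#' analytic Hessian and backtracking; an unbounded dual (diverging
#' parameters) certifies primal infeasibility.
#'
#' @param design a [evaluate_spec()] result.
#' @param summary a [target_summary()] carrying every H moment of the spec.
#' @param options an [eb_options()].
#' @param start optional starting dual (list with `lambda1`, `lambda0`,
#'   `gamma` on the original covariate scale); defaults to the zero vector.
#'   The dual is strictly convex for full-rank designs, so the solution is
#'   invariant to the start.
#' @return A `balancing_solution`: `dual` (lambda1, lambda0, gamma),
#'   `weights` (subject order; `NULL` unless converged), `status` one of
#'   `"converged"`, `"infeasible"`, `"max_iter"`, `value` (dual objective),
#'   `gradient_norm`, `iterations`, `balance_residuals` (a
#'   [check_balance()] report when converged).
#' @export
solve_exact <- function(design, summary, options = eb_options(),
                        start = NULL) {
  al <- align_summary(summary, design$spec)
  if (any(!is.finite(al$values))) stop("non-finite target moment values")
  if (!is.null(start)) {
    p <- ncol(design$H); q <- ncol(design$G)
    mH <- if (options$center && p > 1L)
      colMeans(design$H[, -1L, drop = FALSE]) else numeric(p - 1L)
    mG <- if (options$center && q > 0L) colMeans(design$G) else numeric(q)
    l1 <- unname(start$lambda1); l0 <- unname(start$lambda0)
    gm <- unname(start$gamma)
    l1[1L] <- l1[1L] + sum(l1[-1L] * mH) + sum(gm * mG)
    l0[1L] <- l0[1L] + sum(l0[-1L] * mH) - sum(gm * mG)
    start <- c(l1, l0, gm)
  }
  fit <- eb_core(design$H, design$G, design$A, al$values, options,
                 start = start)
  converged <- fit$status == 0L
  dual <- lapply(fit$dual, function(v) {
    names(v) <- if (length(v) == ncol(design$H))
      colnames(design$H) else colnames(design$G)
    v
  })
  sol <- structure(list(
    dual = dual,
    weights = if (converged) as.numeric(fit$weights),
    status = fit$status_label,
    value = fit$value,
    gradient_norm = fit$grad_norm,
    iterations = fit$iterations,
    balance_residuals = NULL,
    max_weight = if (converged) max(fit$weights)), # near-infeasibility flag
    class = "balancing_solution")
  if (converged) {
    sol$balance_residuals <- check_balance(sol$weights, design, summary)
  }
  sol
}

#' @export
print.balancing_solution <- function(x, ...) {
  cat(sprintf("<balancing_solution> status: %s (gradient max-norm %.2e, %d iterations)\n",
              x$status, x$gradient_norm, x$iterations))
  if (!is.null(x$weights)) {
    cat(sprintf("  weights: n = %d, max = %.3g; max |residual| = %.2e\n",
                length(x$weights), max(x$weights),
                max(abs(x$balance_residuals$residual))))
  }
  if (!is.null(x$relaxation)) cat("  (approximate balancing solution)\n")
  invisible(x)
}

#' Balance-constraint residual report
#'
#' Signed residuals of every balancing constraint for a given weight vector:
#' per-arm H-moment matches against the target values (including the
#' normalization carried by the constant moment) and cross-arm G-moment
#' differences. Standardized residuals divide by the source-sample SD of the
#' moment column (NA for the constant).
#'
#' @param weights positive weight vector in subject order.
#' @param design a [evaluate_spec()] result.
#' @param summary a [target_summary()].
#' @return Data frame with columns `constraint`, `moment`, `residual`,
#'   `standardized`.
#' @export
check_balance <- function(weights, design, summary) {
  al <- align_summary(summary, design$spec)
  n <- design$n
  w1 <- weights[design$S1]; w0 <- weights[design$S0]
  r1 <- as.numeric(crossprod(design$H1, w1)) / n - al$values
  r0 <- as.numeric(crossprod(design$H0, w0)) / n - al$values
  sdH <- c(NA_real_, apply(design$H[, -1L, drop = FALSE], 2L, sd))
  out <- data.frame(
    constraint = rep(c("H_treated", "H_control"), each = length(al$names)),
    moment = rep(al$names, 2L),
    residual = c(r1, r0),
    standardized = c(r1 / sdH, r0 / sdH),
    stringsAsFactors = FALSE)
  if (ncol(design$G)) {
    rg <- (as.numeric(crossprod(design$G1, w1)) -
           as.numeric(crossprod(design$G0, w0))) / n
    sdG <- apply(design$G, 2L, sd)
    out <- rbind(out, data.frame(
      constraint = "G_diff", moment = colnames(design$G),
      residual = rg, standardized = rg / sdG, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
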