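#' Source-estimated correlation of the target moment vector
#'
#' When only the variances of the target moment means are known, their
#' correlation structure is borrowed from the source: the Pearson
#' correlation of the non-constant H columns evaluated on the source
#' subjects, both arms pooled. The constant moment is embedded with the
#' degenerate convention (1 on the diagonal, 0 off).
#'
#' @param design a [evaluate_spec()] result.
#' @return A (K_h + 1) x (K_h + 1) correlation matrix in H-column order.
#' @export
estimate_moment_correlation <- function(design) {
  if (nrow(design$H) < 2L) stop("need at least 2 source rows")
  Hn <- design$H[, -1L, drop = FALSE]
  p <- ncol(Hn)
  R <- diag(1 + p)
  dimnames(R) <- list(colnames(design$H), colnames(design$H))
  if (p == 0L) return(R)
  sds <- apply(Hn, 2L, sd)
  if (any(sds == 0)) {
    stop("moment column(s) with zero source variance: ",
         paste(colnames(Hn)[sds == 0], collapse = ", "))
  }
  Rn <- cor(Hn)
  off <- abs(Rn[upper.tri(Rn)])
  if (p > 1L && any(off > 1 - 1e-10)) {
    warning("perfectly correlated moment columns in the source sample")
  }
  R[-1L, -1L] <- Rn
  R
}

# Assemble the perturbation covariance (user-supplied full matrix wins,
# else D^{1/2} R D^{1/2}) and factor it for fast Gaussian draws. Degenerate
# coordinates keep exactly-zero rows.
perturbation_prep <- function(values, variances, covariance, R) {
  p <- length(values)
  Sigma <- if (!is.null(covariance)) {
    covariance
  } else {
    s <- sqrt(variances)
    R * tcrossprod(s)
  }
  ee <- eigen(Sigma, symmetric = TRUE)
  if (min(ee$values) < -1e-10) {
    stop("perturbation covariance has a negative eigenvalue")
  }
  ev <- pmax(ee$values, 0)
  list(mean = values,
       covariance = Sigma,
       factor = ee$vectors %*% diag(sqrt(ev), p))
}

draw_perturbed <- function(prep) {
  as.numeric(prep$mean + prep$factor %*% rnorm(length(prep$mean)))
}

#' Draw a parametric-bootstrap replicate of the target summary
#'
#' One multivariate-normal draw of the target moment vector, centered at
#' the reported values with covariance `D^{1/2} R D^{1/2}` (D = diagonal of
#' reported variances, R the source-estimated correlation) or the
#' user-supplied full covariance when present. Zero-variance coordinates —
#' the constant moment in particular — pass through unchanged.
#'
#' @param summary a [target_summary()].
#' @param R correlation matrix in the order of `summary$values` (e.g., from
#'   [estimate_moment_correlation()]); ignored when the summary carries a
#'   full covariance. Defaults to independence.
#' @return A new `target_summary` with perturbed values, same variances.
#' @export
perturb_target_summary <- function(summary, R = NULL) {
  p <- length(summary$values)
  if (is.null(R)) R <- diag(p)
  prep <- perturbation_prep(unname(summary$values),
                            unname(summary$variances),
                            if (!is.null(summary$covariance))
                              unname(summary$covariance),
                            R)
  out <- summary
  out$values <- setNames(draw_perturbed(prep), names(summary$values))
  out
}

#' Nonparametric bootstrap of the source sample
#'
#' Resamples the n_s subjects with replacement from the pooled source (arms
#' are not stratified). A replicate with an empty treatment arm is discarded
#' and redrawn so the balancing problem stays well defined.
#'
#' @param sample a [source_sample()].
#' @return A `source_sample` of the same size.
#' @export
bootstrap_source <- function(sample) {
  repeat {
    idx <- sample.int(sample$n, sample$n, replace = TRUE)
    a <- sample$A[idx]
    if (any(a == 1L) && any(a == 0L)) break
  }
  source_sample(sample$X[idx, , drop = FALSE], a, sample$Y[idx])
}

boot_indices <- function(A, n) {
  repeat {
    idx <- sample.int(n, n, replace = TRUE)
    a <- A[idx]
    if (any(a == 1L) && any(a == 0L)) return(idx)
  }
}

new_ci_result <- function(point, taus, B, alpha, infeasible, dropped,
                          method, keep) {
  qs <- quantile(taus, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
  structure(list(point = point, lower = qs[1L], upper = qs[2L],
                 alpha = alpha, B_requested = B, B_used = length(taus),
                 infeasible_count = infeasible, dropped_count = dropped,
                 method = method,
                 replicate_estimates = if (keep) taus),
            class = "ci_result")
}

#' @export
print.ci_result <- function(x, ...) {
  cat(sprintf("<%s> tau_hat = %.4f, %d%% CI (%.4f, %.4f)\n", x$method,
              x$point, round(100 * (1 - x$alpha)), x$lower, x$upper))
  cat(sprintf("  B = %d requested, %d used; infeasible/rescued: %d",
              x$B_requested, x$B_used, x$infeasible_count))
  if (x$dropped_count > 0) cat(sprintf("; dropped: %d", x$dropped_count))
  cat("\n")
  invisible(x)
}

# Shared driver for RPM-CI and RPM-AB. `rescue` switches the treatment of
# replicates whose exact balancing problem is infeasible: drop-and-count
# (RPM-CI) vs. escalate through relaxed solves seeded by the reference dual
# magnitudes (RPM-AB).
rpm_engine <- function(sample, summary, spec, B, alpha, seed, options,
                       rescue, fractions, rule, bootstrap, perturb,
                       keep_replicates, sd_factor = 0.1, fallback = rescue) {
  stopifnot(B >= 1L)
  design <- evaluate_spec(sample, spec)
  al <- align_summary(summary, spec)
  orig <- eb_core(design$H, design$G, design$A, al$values, options)
  fallback_used <- FALSE
  if (orig$status == 0L) {
    ref_dual <- orig$dual
    point <- weighted_ate(orig$weights, sample)$tau_hat
  } else if (fallback) {
    sol <- sd_fallback_solve(design, summary, factor = sd_factor,
                             options = options)
    if (is.null(sol)) {
      stop("balancing is infeasible on the original data even under the ",
           "SD-fallback relaxation")
    }
    fallback_used <- TRUE
    ref_dual <- sol$dual
    point <- weighted_ate(sol$weights, sample)$tau_hat
  } else {
    stop("exact balancing is infeasible on the original data; ",
         "use rpm_ab_ci() (SD-fallback + approximate-balancing rescue)")
  }

  Rhat <- if (is.null(al$covariance)) estimate_moment_correlation(design)
  prep <- perturbation_prep(al$values, al$variances, al$covariance, Rhat)

  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, B)

  n <- design$n
  H <- design$H; G <- design$G; A <- design$A; Y <- sample$Y
  p <- ncol(H); q <- ncol(G)
  taus <- rep(NA_real_, B)
  infeasible <- 0L; dropped <- 0L
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    if (bootstrap) {
      idx <- boot_indices(A, n)
      Hb <- H[idx, , drop = FALSE]; Gb <- G[idx, , drop = FALSE]
      Ab <- A[idx]; Yb <- Y[idx]
    } else {
      Hb <- H; Gb <- G; Ab <- A; Yb <- Y
    }
    vb <- if (perturb) draw_perturbed(prep) else al$values
    fit <- eb_core(Hb, Gb, Ab, vb, options)
    if (fit$status == 0L) {
      sgn <- ifelse(Ab == 1L, 1, -1)
      taus[b] <- sum(sgn * fit$weights * Yb) / n
      next
    }
    infeasible <- infeasible + 1L
    if (!rescue) next
    # escalation: fractions of the reference dual magnitudes first, then
    # the SD heuristic with doubling so moments whose reference multiplier
    # happens to be near zero can still be relaxed
    sdH <- c(0, apply(Hb[, -1L, drop = FALSE], 2L, sd))
    sdG <- if (q) apply(Gb, 2L, sd) else numeric(0)
    deltas <- c(lapply(fractions, function(f) {
      rx <- conform_relaxation(select_relaxation(ref_dual, f, rule = rule),
                               p, q)
      c(rx$delta1, rx$delta1_prime, rx$delta2)
    }), lapply(sd_factor * 2^(0:6), function(fc) {
      fc * c(sdH, sdH, sdG)
    }))
    rescued <- FALSE
    for (delta in deltas) {
      afit <- eb_approx_core(Hb, Gb, Ab, vb, delta, options)
      w <- afit$weights
      r1 <- as.numeric(crossprod(Hb[Ab == 1L, , drop = FALSE],
                                 w[Ab == 1L])) / n - vb
      r0 <- as.numeric(crossprod(Hb[Ab == 0L, , drop = FALSE],
                                 w[Ab == 0L])) / n - vb
      rg <- if (q) (as.numeric(crossprod(Gb[Ab == 1L, , drop = FALSE],
                                         w[Ab == 1L])) -
                    as.numeric(crossprod(Gb[Ab == 0L, , drop = FALSE],
                                         w[Ab == 0L]))) / n else numeric(0)
      if (all(abs(c(r1, r0, rg)) <= delta + 1e-6)) {
        sgn <- ifelse(Ab == 1L, 1, -1)
        taus[b] <- sum(sgn * w * Yb) / n
        rescued <- TRUE
        break
      }
    }
    if (!rescued) dropped <- dropped + 1L
  }
  taus <- taus[!is.na(taus)]
  if (!rescue && length(taus) < 50L) {
    warning("fewer than 50 feasible perturbation replicates; ",
            "consider rpm_ab_ci() (approximate-balancing rescue)")
  }
  if (rescue && dropped > 0L) {
    warning(sprintf("%d replicate(s) unsolvable at the largest relaxation fraction were dropped",
                    dropped))
  }
  out <- new_ci_result(point, taus, B, alpha, infeasible, dropped,
                       if (rescue) "RPM-AB" else "RPM-CI", keep_replicates)
  out$fallback_used <- fallback_used
  out
}

#' Resampling-based perturbation confidence interval (exact balancing)
#'
#' For each of B replicates the source sample is bootstrapped (with
#' replacement, arms pooled) and the target moment vector is perturbed by a
#' multivariate-normal draw whose variances come from the target summary
#' and whose correlation is borrowed from the source; exact balancing
#' weights and the weighted ATE are recomputed on the replicate. The CI is
#' the empirical `alpha/2` and `1 - alpha/2` percentile interval (linear
#' interpolation) of the feasible replicate estimates; replicates whose
#' exact balancing problem is infeasible are dropped and counted.
#'
#' @param sample a [source_sample()].
#' @param summary a [target_summary()] (variances required; binary moments
#'   may auto-fill).
#' @param spec a [balance_spec()].
#' @param B number of perturbation replicates.
#' @param alpha 1 - confidence level.
#' @param seed master seed; it spawns an independent substream per
#'   replicate, so results are reproducible and order-independent.
#' @param options an [eb_options()].
#' @param bootstrap,perturb diagnostic switches disabling the source
#'   bootstrap / target perturbation (both `TRUE` for the real method).
#' @param keep_replicates retain the replicate estimates in the result.
#' @param fallback when the exact solve on the original data is infeasible,
#'   take the point estimate from the SD-fallback relaxed solution instead
#'   of erroring (replicates are still exact-balancing only, dropped and
#'   counted when infeasible); `fallback_used` in the result records it.
#' @return A `ci_result`: `point` (estimate on the original data), `lower`,
#'   `upper`, `B_requested`, `B_used`, `infeasible_count`, `method`,
#'   optionally `replicate_estimates`.
#' @export
rpm_ci <- function(sample, summary, spec, B = 1000L, alpha = 0.05,
                   seed = NULL, options = eb_options(), bootstrap = TRUE,
                   perturb = TRUE, keep_replicates = TRUE,
                   fallback = FALSE) {
  rpm_engine(sample, summary, spec, B, alpha, seed, options,
             rescue = FALSE, fractions = NULL, rule = "proportional",
             bootstrap = bootstrap, perturb = perturb,
             keep_replicates = keep_replicates, fallback = fallback)
}

#' Resampling-based perturbation CI with approximate-balancing rescue
#'
#' Identical to [rpm_ci()] except that replicates whose exact balancing
#' problem is infeasible are rescued: relaxation magnitudes are taken as
#' escalating fractions of the reference dual (the exact solve on the
#' original data, or the SD-fallback solution when even that is infeasible)
#' and the relaxed problem is solved at each fraction until it converges;
#' if the whole schedule fails (e.g., a needed multiplier is near zero on
#' the original data), slacks escalate through the SD heuristic
#' (`sd_factor` times each moment's replicate SD, doubling). Every
#' replicate then contributes to the percentile interval;
#' `infeasible_count` reports how many needed rescue and `dropped_count`
#' how many failed every relaxation stage.
#'
#' @inheritParams rpm_ci
#' @param fractions escalation schedule of relaxation fractions.
#' @param rule relaxation rule, see [select_relaxation()].
#' @param sd_factor starting factor for the SD fallback on the original
#'   data.
#' @return A `ci_result`; `fallback_used` records whether the point
#'   estimate came from the SD-fallback relaxed solution.
#' @export
rpm_ab_ci <- function(sample, summary, spec, B = 1000L, alpha = 0.05,
                      seed = NULL, options = eb_options(),
                      fractions = c(0.05, 0.1, 0.2, 0.4, 0.8),
                      rule = "proportional", sd_factor = 0.1,
                      bootstrap = TRUE, perturb = TRUE,
                      keep_replicates = TRUE) {
  rpm_engine(sample, summary, spec, B, alpha, seed, options,
             rescue = TRUE, fractions = fractions, rule = rule,
             bootstrap = bootstrap, perturb = perturb,
             keep_replicates = keep_replicates, sd_factor = sd_factor)
}
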