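test_that("moment correlation is the pooled Pearson correlation", {
  # 4-point set with hand-computed correlation:
  # cov = 1/3, var(x1) = 2/3, var(x2) = 1/3 -> r = 1/sqrt(2)
  X <- cbind(x1 = c(0, 1, 1, 2), x2 = c(0, 0, 1, 1))
  s <- source_sample(X, c(1L, 0L, 1L, 0L), rnorm(4))
  d <- evaluate_spec(s, balance_spec(h = c("x1", "x2")))
  R <- estimate_moment_correlation(d)
  expect_equal(dim(R), c(3L, 3L))
  expect_equal(R["x1", "x2"], 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(R["(intercept)", ], c(`(intercept)` = 1, x1 = 0, x2 = 0))
  # single moment embeds as the 1x1 identity
  d1 <- evaluate_spec(s, balance_spec(h = "x1"))
  expect_equal(unname(estimate_moment_correlation(d1)), diag(2))
  # perfectly collinear H columns warn; a constant H column errors
  x <- c(0, 1, 2, 3)
  d2 <- structure(list(H = cbind(`(intercept)` = 1, x1 = x, x3 = 2 * x),
                       n = 4), class = "design_matrices")
  expect_warning(estimate_moment_correlation(d2), "correlated")
  d3 <- structure(list(H = cbind(`(intercept)` = 1, x1 = x,
                                 x2 = rep(1, 4)), n = 4),
                  class = "design_matrices")
  expect_error(estimate_moment_correlation(d3), "zero source variance.*x2")
})

test_that("target perturbation has the advertised distribution", {
  vals <- c(x1 = 0.4, x2 = -0.2)
  vars <- c(x1 = 0.04, x2 = 0.09)
  ts <- target_summary(vals, vars, n_t = 100)
  R <- diag(3); R[2, 3] <- R[3, 2] <- 0.6
  set.seed(5)
  draws <- t(replicate(20000, perturb_target_summary(ts, R)$values))
  expect_true(all(draws[, 1] == 1))  # constant coordinate untouched
  se <- sqrt(vars / 20000)
  expect_lt(abs(mean(draws[, 2]) - 0.4), 4 * se[1])
  expect_lt(abs(mean(draws[, 3]) + 0.2), 4 * se[2])
  emp_cov <- cov(draws[, 2:3])
  want <- 0.6 * sqrt(0.04 * 0.09)
  expect_lt(abs(emp_cov[1, 2] - want) / want, 0.05)
  expect_lt(abs(emp_cov[1, 1] - 0.04) / 0.04, 0.05)
  # degenerate Gaussian: all variances zero -> identity perturbation
  ts0 <- target_summary(vals, c(x1 = 0, x2 = 0), n_t = 100)
  expect_equal(perturb_target_summary(ts0, R)$values, ts0$values)
  # fixed seed -> identical replicate sequence
  set.seed(9); a <- replicate(5, perturb_target_summary(ts, R)$values)
  set.seed(9); b <- replicate(5, perturb_target_summary(ts, R)$values)
  expect_identical(a, b)
})

test_that("a negative-eigenvalue covariance is rejected", {
  vals <- c(x1 = 0, x2 = 0)
  bad <- matrix(c(1, 2, 2, 1), 2, 2)  # eigenvalues 3, -1
  ts <- target_summary(vals, c(x1 = 1, x2 = 1), n_t = 10)
  expect_error(target_summary(vals, covariance = bad, n_t = 10),
               "positive semidefinite")
  ts$covariance <- rbind(0, cbind(0, bad))
  expect_error(perturb_target_summary(ts), "negative eigenvalue")
  # a valid full covariance defaults the variances to its diagonal
  ok <- matrix(c(1, 0.5, 0.5, 2), 2, 2)
  ts2 <- target_summary(vals, covariance = ok, n_t = 10)
  expect_equal(unname(ts2$variances), c(0, 1, 2))
})

test_that("the source bootstrap is reproducible and guards empty arms", {
  inst <- make_instance(n = 5, K_h = 1, K_g = 0, seed = 1)
  set.seed(3); b1 <- bootstrap_source(inst$sample)
  set.seed(3); b2 <- bootstrap_source(inst$sample)
  expect_identical(b1$X, b2$X)
  expect_identical(b1$A, b2$A)
  # one subject per arm: every replicate keeps both after redraws
  tiny <- source_sample(matrix(c(0, 1), ncol = 1,
                               dimnames = list(NULL, "x")),
                        c(1L, 0L), c(0, 1))
  set.seed(11)
  for (i in 1:25) {
    bb <- bootstrap_source(tiny)
    expect_true(any(bb$A == 1L) && any(bb$A == 0L))
  }
  # bootstrap mean of Y concentrates on the sample mean
  set.seed(13)
  inst2 <- make_instance(n = 60, K_h = 1, K_g = 0, seed = 2)
  ms <- replicate(2000, mean(bootstrap_source(inst2$sample)$Y))
  se <- sd(inst2$sample$Y) / sqrt(inst2$sample$n) / sqrt(2000)
  expect_lt(abs(mean(ms) - mean(inst2$sample$Y)), 4 * se)
})

test_that("the degenerate pipeline collapses to the point estimate", {
  inst <- make_instance(n = 50, K_h = 2, K_g = 1, seed = 19)
  ci <- rpm_ci(inst$sample, inst$summary, inst$spec, B = 60, seed = 1,
               bootstrap = FALSE, perturb = FALSE)
  expect_equal(ci$lower, ci$point, tolerance = 1e-10)
  expect_equal(ci$upper, ci$point, tolerance = 1e-10)
  expect_equal(ci$B_used, 60L)
  expect_identical(ci$infeasible_count, 0L)
})

test_that("replicate estimates are deterministic under a master seed", {
  inst <- make_instance(n = 200, K_h = 2, K_g = 1, seed = 10, tilt = 0.1)
  c1 <- rpm_ci(inst$sample, inst$summary, inst$spec, B = 80, seed = 42)
  c2 <- rpm_ci(inst$sample, inst$summary, inst$spec, B = 80, seed = 42)
  expect_identical(c1$replicate_estimates, c2$replicate_estimates)
  expect_identical(c(c1$lower, c1$upper), c(c2$lower, c2$upper))
  # RPM-AB equals RPM-CI replicate-for-replicate when no rescue triggers
  a1 <- rpm_ab_ci(inst$sample, inst$summary, inst$spec, B = 80, seed = 42)
  expect_identical(a1$infeasible_count, 0L)
  expect_identical(a1$replicate_estimates, c1$replicate_estimates)
})

test_that("percentile interval brackets the replicate median and collapses as alpha grows", {
  inst <- make_instance(n = 50, K_h = 2, K_g = 1, seed = 25)
  ci <- rpm_ci(inst$sample, inst$summary, inst$spec, B = 120, seed = 7)
  med <- median(ci$replicate_estimates)
  expect_lte(ci$lower, med)
  expect_gte(ci$upper, med)
  wide <- rpm_ci(inst$sample, inst$summary, inst$spec, B = 120, seed = 7,
                 alpha = 0.9)
  expect_lt(wide$upper - wide$lower, ci$upper - ci$lower)
})

test_that("CI width grows with the perturbation variance", {
  inst <- make_instance(n = 60, K_h = 2, K_g = 1, seed = 33)
  ci1 <- rpm_ci(inst$sample, inst$summary, inst$spec, B = 250, seed = 3)
  inflated <- target_summary(inst$summary$values[-1],
                             4 * inst$summary$variances[-1],
                             n_t = inst$summary$n_t)
  ci4 <- rpm_ci(inst$sample, inflated, inst$spec, B = 250, seed = 3)
  expect_gte(ci4$upper - ci4$lower, ci1$upper - ci1$lower)
})

test_that("rescued replicates obey the relaxation actually used", {
  # small noisy design: rescues certain to trigger
  set.seed(77)
  d <- design_preset("table3_linear_T1M2")
  st <- generate_study(d)
  ci <- rpm_ci(st$source, st$target_summary, default_balance_spec(),
               B = 120, seed = 5)
  ab <- rpm_ab_ci(st$source, st$target_summary, default_balance_spec(),
                  B = 120, seed = 5)
  expect_identical(ab$infeasible_count, ci$infeasible_count)
  expect_gte(ab$B_used, ci$B_used)
  expect_equal(ab$B_used + ab$dropped_count, 120L)
  # feasible replicates agree across the two methods under the same seed
  if (ci$B_used < 120L && ci$B_used > 0L) {
    expect_true(all(ci$replicate_estimates %in% ab$replicate_estimates))
  }
})
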