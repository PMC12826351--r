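test_that("dual objective at the zero dual equals its closed form", {
  inst <- make_instance(n = 20, K_h = 2, K_g = 1, seed = 3)
  zero <- list(lambda1 = rep(0, 3), lambda0 = rep(0, 3), gamma = 0)
  ev <- dual_objective(zero, inst$design, inst$summary)
  # (1/ns) sum_S1 1 + (1/ns) sum_S0 1 - 0 = 1
  expect_equal(ev$value, 1)
  # gradient at zero: unweighted arm moments minus targets
  al <- ebtransport:::align_summary(inst$summary, inst$spec)
  expect_equal(ev$gradient[1:3],
               as.numeric(colSums(inst$design$H1)) / inst$design$n -
                 al$values)
})

test_that("analytic gradient matches central finite differences", {
  inst <- make_instance(n = 5, K_h = 2, K_g = 1, seed = 11)
  set.seed(12)
  theta <- rnorm(7, sd = 0.3)
  dual <- list(lambda1 = theta[1:3], lambda0 = theta[4:6],
               gamma = theta[7])
  ev <- dual_objective(dual, inst$design, inst$summary)
  eps <- 1e-6
  fd <- vapply(seq_along(theta), function(j) {
    up <- theta; up[j] <- up[j] + eps
    dn <- theta; dn[j] <- dn[j] - eps
    mk <- function(v) list(lambda1 = v[1:3], lambda0 = v[4:6],
                           gamma = v[7])
    (dual_objective(mk(up), inst$design, inst$summary)$value -
       dual_objective(mk(dn), inst$design, inst$summary)$value) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(ev$gradient - fd)), 1e-5)
})

test_that("the symmetric toy instance has its closed-form solution", {
  toy <- toy_instance(target = 0)
  sol <- solve_exact(toy$design, toy$summary)
  expect_equal(sol$status, "converged")
  expect_equal(sol$weights, rep(2, 4), tolerance = 1e-8)
  expect_equal(unname(sol$dual$lambda1), c(log(2), 0), tolerance = 1e-8)
  expect_equal(unname(sol$dual$lambda0), c(log(2), 0), tolerance = 1e-8)
  # stationarity at the optimum
  ev <- dual_objective(sol$dual, toy$design, toy$summary)
  expect_lt(max(abs(ev$gradient)), 1e-8)
  # descent from the cold start
  expect_lte(sol$value,
             dual_objective(list(lambda1 = c(0, 0), lambda0 = c(0, 0),
                                 gamma = numeric(0)),
                            toy$design, toy$summary)$value)
})

test_that("a target outside the source support is declared infeasible", {
  toy <- toy_instance(target = 5)
  sol <- solve_exact(toy$design, toy$summary)
  expect_equal(sol$status, "infeasible")
  expect_null(sol$weights)
})

test_that("converged solutions satisfy every balance constraint", {
  for (seed in c(2, 9, 31)) {
    inst <- make_instance(n = 60, K_h = 3, K_g = 2, seed = seed)
    sol <- solve_exact(inst$design, inst$summary)
    expect_equal(sol$status, "converged")
    expect_true(all(sol$weights > 0))
    expect_lt(max(abs(sol$balance_residuals$residual)), 1e-6)
    # per-arm normalization: (1/ns) sum_arm w = 1
    n <- inst$design$n
    expect_equal(sum(sol$weights[inst$design$S1]) / n, 1,
                 tolerance = 1e-8)
    expect_equal(sum(sol$weights[inst$design$S0]) / n, 1,
                 tolerance = 1e-8)
  }
})

test_that("weights_from_dual reproduces the solver's weights", {
  inst <- make_instance(n = 40, K_h = 2, K_g = 1, seed = 5)
  sol <- solve_exact(inst$design, inst$summary)
  expect_equal(weights_from_dual(sol$dual, inst$design), sol$weights,
               tolerance = 1e-10)
  # zero dual -> unit weights; intercept-only tilt scales them
  zero <- list(lambda1 = rep(0, 3), lambda0 = rep(0, 3), gamma = 0)
  expect_equal(weights_from_dual(zero, inst$design),
               rep(1, inst$design$n))
  tilt <- zero; tilt$lambda1[1] <- log(2)
  w <- weights_from_dual(tilt, inst$design)
  expect_equal(w[inst$design$S1], rep(2, length(inst$design$S1)))
})

test_that("check_balance on uniform weights returns raw mean differences", {
  inst <- make_instance(n = 30, K_h = 2, K_g = 1, seed = 7)
  al <- ebtransport:::align_summary(inst$summary, inst$spec)
  n <- inst$design$n
  # arm-normalized uniform weights: (1/n) sum_arm w = 1
  w <- rep(n / length(inst$design$S1), n)
  w[inst$design$S0] <- n / length(inst$design$S0)
  rep_ <- check_balance(w, inst$design, inst$summary)
  h1 <- rep_[rep_$constraint == "H_treated", ]
  expect_equal(h1$residual[2],
               mean(inst$design$H1[, 2]) - al$values[2], tolerance = 1e-12)
})

test_that("the solution is invariant to the starting point", {
  inst <- make_instance(n = 50, K_h = 3, K_g = 2, seed = 13)
  s0 <- solve_exact(inst$design, inst$summary)
  set.seed(99)
  warm <- list(lambda1 = rnorm(4, sd = 0.5), lambda0 = rnorm(4, sd = 0.5),
               gamma = rnorm(2, sd = 0.5))
  s1 <- solve_exact(inst$design, inst$summary, start = warm)
  expect_equal(s1$value, s0$value, tolerance = 1e-8)
  expect_lt(max(abs(s1$weights - s0$weights)), 1e-5)
})

test_that("rescaling a covariate rescales its multiplier, not the weights", {
  inst <- make_instance(n = 40, K_h = 2, K_g = 1, seed = 17)
  sol <- solve_exact(inst$design, inst$summary)
  cc <- 10
  X2 <- inst$sample$X
  X2[, "x1"] <- cc * X2[, "x1"]
  s2 <- source_sample(X2, inst$sample$A, inst$sample$Y)
  vals <- inst$summary$values[-1]
  vals["x1"] <- cc * vals["x1"]
  vars <- inst$summary$variances[-1]
  vars["x1"] <- cc^2 * vars["x1"]
  sum2 <- target_summary(vals, vars, n_t = inst$summary$n_t)
  sol2 <- solve_exact(evaluate_spec(s2, inst$spec), sum2)
  expect_lt(max(abs(sol2$weights - sol$weights)), 1e-8)
  expect_equal(unname(sol2$dual$lambda1["x1"]),
               unname(sol$dual$lambda1["x1"]) / cc, tolerance = 1e-7)
})

test_that("centering is a pure reparametrization", {
  inst <- make_instance(n = 45, K_h = 3, K_g = 1, seed = 23)
  on <- solve_exact(inst$design, inst$summary, eb_options(center = TRUE))
  off <- solve_exact(inst$design, inst$summary, eb_options(center = FALSE))
  expect_equal(on$weights, off$weights, tolerance = 1e-7)
  expect_equal(on$dual$lambda1, off$dual$lambda1, tolerance = 1e-6)
})
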