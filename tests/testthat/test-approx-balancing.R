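test_that("an all-zero relaxation reproduces the exact solution", {
  inst <- make_instance(n = 40, K_h = 2, K_g = 1, seed = 4)
  exact <- solve_exact(inst$design, inst$summary)
  zero <- relaxation_spec(rep(0, 3), rep(0, 3), 0)
  ap <- solve_approx(inst$design, inst$summary, zero)
  expect_equal(ap$status, exact$status)
  expect_equal(ap$weights, exact$weights, tolerance = 1e-8)
  # and infeasibility semantics are preserved too
  toy <- toy_instance(target = 5)
  expect_equal(solve_approx(toy$design, toy$summary,
                            relaxation_spec(c(0, 0)))$status,
               "infeasible")
})

test_that("slack restores feasibility on the out-of-hull toy", {
  toy <- toy_instance(target = 5)
  rx <- relaxation_spec(c(0, 4.5))
  sol <- solve_approx(toy$design, toy$summary, rx)
  expect_equal(sol$status, "converged")
  n <- toy$design$n
  wm <- sum(sol$weights[toy$design$S1] * toy$design$H1[, 2]) / n
  expect_lte(abs(wm - 5), 4.5 + 1e-6)
  # normalization stays exact
  expect_equal(sum(sol$weights[toy$design$S1]) / n, 1, tolerance = 1e-6)
})

test_that("relaxed solutions respect their slack bounds", {
  inst <- make_instance(n = 40, K_h = 3, K_g = 2, seed = 21)
  rx <- relaxation_spec(c(0, 0.05, 0.1, 0.02), c(0, 0.05, 0.1, 0.02),
                        c(0.03, 0.03))
  sol <- solve_approx(inst$design, inst$summary, rx)
  expect_equal(sol$status, "converged")
  bounds <- c(sol$relaxation$delta1, sol$relaxation$delta1_prime,
              sol$relaxation$delta2)
  expect_true(all(abs(sol$balance_residuals$residual) <= bounds + 1e-6))
})

test_that("the penalized optimum is monotone in the slack", {
  # the penalty delta' |lambda| is pointwise nondecreasing in delta, so the
  # minimized objective is too (while the primal entropy optimum decreases
  # as the feasible set widens)
  inst <- make_instance(n = 35, K_h = 2, K_g = 1, seed = 8)
  vals <- vapply(c(0.01, 0.05, 0.2, 0.8), function(dl) {
    rx <- relaxation_spec(rep(dl, 2), rep(dl, 2), dl)
    solve_approx(inst$design, inst$summary, rx)$value
  }, numeric(1))
  expect_true(all(diff(vals) >= -1e-8))
  entropies <- vapply(c(0.01, 0.05, 0.2, 0.8), function(dl) {
    rx <- relaxation_spec(rep(dl, 2), rep(dl, 2), dl)
    entropy_of(solve_approx(inst$design, inst$summary, rx)$weights)
  }, numeric(1))
  expect_true(all(diff(entropies) <= 1e-8))
})

test_that("active slacks bind and inactive multipliers vanish", {
  # complementary slackness of the L1-penalized dual
  inst <- make_instance(n = 45, K_h = 3, K_g = 1, seed = 14)
  rx <- relaxation_spec(c(0, 0.04, 0.04, 0.04), c(0, 0.04, 0.04, 0.04),
                        0.04)
  sol <- solve_approx(inst$design, inst$summary, rx)
  expect_equal(sol$status, "converged")
  bounds <- c(sol$relaxation$delta1, sol$relaxation$delta1_prime,
              sol$relaxation$delta2)
  mult <- c(sol$dual$lambda1, sol$dual$lambda0, sol$dual$gamma)
  resid <- sol$balance_residuals$residual
  for (k in which(bounds > 0)) {
    if (abs(mult[k]) > 1e-5) {
      expect_equal(abs(resid[k]), bounds[k], tolerance = 1e-4)
    }
    if (abs(resid[k]) < bounds[k] - 1e-5) {
      expect_lt(abs(mult[k]), 1e-5)
    }
  }
})

test_that("select_relaxation implements both rules", {
  dual <- list(lambda1 = c(0.3, -2.0, 0.5), lambda0 = c(0.1, 1.0, -0.2),
               gamma = c(0.4))
  rx <- select_relaxation(dual, 0.1)
  expect_equal(rx$delta1, c(0, 0.2, 0.05))
  expect_equal(rx$delta1_prime, c(0, 0.1, 0.02))
  expect_equal(rx$delta2, 0.04)
  expect_equal(select_relaxation(dual, 0)$delta1, c(0, 0, 0))
  inv <- select_relaxation(dual, 0.1, rule = "inverse", cap = 1)
  expect_equal(inv$delta1, c(0, 0.05, 0.2))
  expect_equal(select_relaxation(list(lambda1 = c(0.5, 1e-12),
                                      lambda0 = c(0.5, 0),
                                      gamma = numeric(0)),
                                 0.1, rule = "inverse",
                                 cap = 3)$delta1[2], 3)
  expect_error(select_relaxation(dual, -0.1), "nonnegative")
})

test_that("the SD fallback sets slacks from source spread and rescues", {
  X <- matrix(c(rnorm(50, sd = 2)), 50, 1, dimnames = list(NULL, "x"))
  X[, 1] <- 2 * scale(X[, 1])[, 1]  # exact SD 2
  s <- source_sample(X, rep(c(1L, 0L), 25), rnorm(50))
  spec <- balance_spec(h = "x")
  d <- evaluate_spec(s, spec)
  rx <- sd_fallback_relaxation(d, factor = 0.1)
  expect_equal(rx$delta1, c(0, 0.2), tolerance = 1e-12)
  expect_equal(rx$delta1[1], 0)  # constant moment stays exact
  # a target far outside the hull becomes solvable at some doubling
  ts <- target_summary(c(x = max(X) + 1), c(x = 0.01), n_t = 100)
  expect_equal(solve_exact(d, ts)$status, "infeasible")
  sol <- sd_fallback_solve(d, ts, factor = 0.1)
  expect_false(is.null(sol))
  expect_equal(sol$status, "converged")
  bounds <- c(sol$relaxation$delta1, sol$relaxation$delta1_prime)
  expect_true(all(abs(sol$balance_residuals$residual) <= bounds + 1e-6))
})

test_that("fraction escalation terminates on an infeasible instance", {
  toy <- toy_instance(target = 1.5)  # outside the hull mean range
  exact <- solve_exact(toy$design, toy$summary)
  expect_equal(exact$status, "infeasible")
  # seed the escalation with the dual of a solvable neighbour
  near <- toy_instance(target = 0.5)
  ref <- solve_exact(near$design, near$summary)
  sol <- solve_with_escalation(toy$design, toy$summary, ref$dual,
                               fractions = c(0.05, 0.1, 0.2, 0.4, 0.8,
                                             1.6, 3.2))
  expect_false(is.null(sol))
  expect_equal(sol$status, "converged")
  expect_true(attr(sol, "fraction") > 0)
})

test_that("the relaxed optimum approaches the exact one as slack shrinks", {
  inst <- make_instance(n = 30, K_h = 2, K_g = 1, seed = 6)
  exact <- solve_exact(inst$design, inst$summary)
  vals <- vapply(c(0.1, 0.01, 0.001, 1e-5), function(dl) {
    solve_approx(inst$design, inst$summary,
                 relaxation_spec(rep(dl, 2), rep(dl, 2), dl))$value
  }, numeric(1))
  gaps <- abs(vals - exact$value)
  expect_true(all(diff(gaps) < 1e-8))
  expect_lt(gaps[4], 1e-5)
})
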