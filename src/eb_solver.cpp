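// Damped-Newton solver for the entropy-balancing dual and fast
// objective/gradient evaluations used by the L1-penalized (relaxed) dual.
//
// Parametrization: theta = (lambda1, lambda0, gamma) stacked.  Each source
// subject contributes one row z_i of Z: [H_i, 0, G_i] if treated,
// [0, H_i, -G_i] if control.  The dual objective is
//   f(theta) = (1/n_s) sum_i exp(z_i' theta) - c' theta,
// with c = (Hbar_T, Hbar_T, 0).  Its gradient is (1/n_s) Z' exp(Z theta) - c
// and its Hessian (1/n_s) Z' diag(exp(Z theta)) Z, positive definite for
// full-rank Z, so Newton with backtracking converges globally on feasible
// instances.  On infeasible instances (target moments outside the convex
// hull of the resampled source moments) the dual is unbounded below and the
// iterates diverge; that divergence is the infeasibility certificate.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double ETA_CAP = 500.0;  // exp overflow guard

static double dual_value(const mat& Z, const vec& cvec, const vec& theta,
                         vec& eta, vec& u, bool& ok) {
  eta = Z * theta;
  if (eta.max() > ETA_CAP) { ok = false; return datum::inf; }
  ok = true;
  u = exp(eta);
  return mean(u) - dot(cvec, theta);
}

// [[Rcpp::export(name = ".eb_newton_cpp")]]
Rcpp::List eb_newton_cpp(const arma::mat& Z, const arma::vec& cvec,
                         double tol, int max_iter, double div_bound,
                         double infeas_grad, const arma::vec& start) {
  const double n = static_cast<double>(Z.n_rows);
  const uword d = Z.n_cols;
  vec theta = start, eta, u;
  if (theta.n_elem != d) theta = vec(d, fill::zeros);
  bool ok;
  double f = dual_value(Z, cvec, theta, eta, u, ok);
  vec g = Z.t() * u / n - cvec;
  int status = 2;  // 0 converged, 1 infeasible, 2 max_iter
  int iter = 0;
  int stall = 0;   // consecutive machine-precision objective decreases

  for (iter = 0; iter < max_iter; ++iter) {
    double gmax = norm(g, "inf");
    if (gmax <= tol) { status = 0; break; }
    // objective stagnates at machine precision with the gradient already
    // far inside the residual tolerance: numerically at the optimum
    if (stall >= 3) {
      status = (gmax <= infeas_grad) ? 0
               : (norm(theta, "inf") > div_bound ? 1 : 2);
      break;
    }
    if (norm(theta, "inf") > div_bound && gmax > infeas_grad) {
      status = 1; break;
    }
    mat Hs = Z.t() * (Z.each_col() % u) / n;
    vec step;
    bool solved = solve(step, Hs, -g, solve_opts::likely_sympd + solve_opts::no_approx);
    if (!solved || !step.is_finite()) {
      // ridge rescue for a numerically singular Hessian
      double ridge = 1e-10 * (1.0 + trace(Hs) / d);
      for (int k = 0; k < 8 && (!solved || !step.is_finite()); ++k) {
        solved = solve(step, Hs + ridge * eye(d, d), -g,
                       solve_opts::likely_sympd + solve_opts::no_approx);
        ridge *= 100.0;
      }
      if (!solved || !step.is_finite()) step = -g;  // gradient fallback
    }
    double slope = dot(g, step);
    if (slope >= 0) { step = -g; slope = dot(g, step); }
    // Armijo backtracking
    double t = 1.0, fnew = datum::inf;
    vec theta_new, eta_new, u_new;
    bool accepted = false;
    for (int ls = 0; ls < 60; ++ls) {
      theta_new = theta + t * step;
      bool fin;
      fnew = dual_value(Z, cvec, theta_new, eta_new, u_new, fin);
      if (fin && fnew <= f + 1e-4 * t * slope) { accepted = true; break; }
      t *= 0.5;
    }
    if (!accepted) {
      // no descent achievable: either at the optimum to machine precision
      // or diverging along an unbounded direction
      status = (norm(theta, "inf") > div_bound) ? 1
               : (gmax <= infeas_grad ? 0 : 2);
      break;
    }
    stall = (f - fnew <= 1e-14 * (1.0 + std::abs(f))) ? stall + 1 : 0;
    theta = theta_new; f = fnew; u = u_new;
    g = Z.t() * u / n - cvec;
  }
  if (status == 2 && norm(theta, "inf") > div_bound) status = 1;

  return Rcpp::List::create(
    Rcpp::Named("theta") = theta,
    Rcpp::Named("weights") = u,
    Rcpp::Named("value") = f,
    Rcpp::Named("grad_norm") = norm(g, "inf"),
    Rcpp::Named("iterations") = iter,
    Rcpp::Named("status") = status);
}

// Orthant-wise damped Newton for the L1-penalized dual
//   F(theta) = mean(exp(Z theta)) - c' theta + delta' |theta|.
// The pseudo-gradient replaces the L1 subdifferential coordinate-wise,
// the Newton direction uses the exact smooth Hessian and is sign-aligned
// with the steepest-descent direction, and each trial point is projected
// onto the working orthant (coordinates with delta = 0 are unpenalized
// and never projected). Suited to the small parameter dimensions here.
static double pen_value(const mat& Z, const vec& cvec, const vec& delta,
                        const vec& theta, vec& u, bool& ok) {
  vec eta = Z * theta;
  if (eta.max() > ETA_CAP) { ok = false; return datum::inf; }
  ok = true;
  u = exp(eta);
  return mean(u) - dot(cvec, theta) + dot(delta, abs(theta));
}

// [[Rcpp::export(name = ".eb_orthant_cpp")]]
Rcpp::List eb_orthant_cpp(const arma::mat& Z, const arma::vec& cvec,
                          const arma::vec& delta, double tol, int max_iter,
                          double div_bound, double infeas_grad) {
  const double n = static_cast<double>(Z.n_rows);
  const uword d = Z.n_cols;
  vec theta(d, fill::zeros), u;
  bool ok;
  double F = pen_value(Z, cvec, delta, theta, u, ok);
  int status = 2, iter = 0, stall = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    vec g = Z.t() * u / n - cvec;
    vec pg(d);
    for (uword k = 0; k < d; ++k) {
      if (theta(k) > 0)       pg(k) = g(k) + delta(k);
      else if (theta(k) < 0)  pg(k) = g(k) - delta(k);
      else if (g(k) + delta(k) < 0) pg(k) = g(k) + delta(k);
      else if (g(k) - delta(k) > 0) pg(k) = g(k) - delta(k);
      else                    pg(k) = 0.0;
    }
    double gmax = norm(pg, "inf");
    if (gmax <= tol) { status = 0; break; }
    if (stall >= 8) {
      status = (gmax <= infeas_grad) ? 0
               : (norm(theta, "inf") > div_bound ? 1 : 2);
      break;
    }
    if (norm(theta, "inf") > div_bound && gmax > infeas_grad) {
      status = 1; break;
    }
    mat Hs = Z.t() * (Z.each_col() % u) / n;
    vec step;
    bool solved = solve(step, Hs, -pg,
                        solve_opts::likely_sympd + solve_opts::no_approx);
    if (!solved || !step.is_finite()) step = -pg;
    // keep the direction in the descent half-space coordinate-wise, and
    // pin coordinates resting inside their subdifferential interval
    for (uword k = 0; k < d; ++k) {
      if (step(k) * pg(k) > 0) step(k) = 0.0;
      if (theta(k) == 0 && pg(k) == 0) step(k) = 0.0;
    }
    if (norm(step, "inf") == 0) step = -pg;
    // working orthant: current sign, or the sign the pseudo-gradient
    // pushes a zero coordinate toward
    vec xi(d);
    for (uword k = 0; k < d; ++k) {
      xi(k) = (theta(k) != 0) ? ((theta(k) > 0) ? 1.0 : -1.0)
                              : ((pg(k) < 0) ? 1.0 : (pg(k) > 0 ? -1.0
                                                                : 0.0));
    }
    double t = 1.0;
    bool accepted = false;
    vec theta_new, u_new;
    double Fnew = datum::inf;
    for (int ls = 0; ls < 60; ++ls) {
      theta_new = theta + t * step;
      for (uword k = 0; k < d; ++k) {
        if (delta(k) > 0 && xi(k) != 0 && theta_new(k) * xi(k) < 0) {
          theta_new(k) = 0.0;
        }
      }
      bool fin;
      Fnew = pen_value(Z, cvec, delta, theta_new, u_new, fin);
      double pred = dot(pg, theta_new - theta);
      if (fin && Fnew <= F + 1e-4 * std::min(pred, 0.0)) {
        accepted = true; break;
      }
      t *= 0.5;
    }
    if (!accepted) {
      status = (norm(theta, "inf") > div_bound) ? 1
               : (gmax <= infeas_grad ? 0 : 2);
      break;
    }
    stall = (F - Fnew <= 1e-14 * (1.0 + std::abs(F))) ? stall + 1 : 0;
    theta = theta_new; F = Fnew; u = u_new;
  }
  if (status == 2 && norm(theta, "inf") > div_bound) status = 1;

  vec gfin = Z.t() * u / n - cvec;
  return Rcpp::List::create(
    Rcpp::Named("theta") = theta,
    Rcpp::Named("weights") = u,
    Rcpp::Named("value") = F,
    Rcpp::Named("smooth_grad") = gfin,
    Rcpp::Named("iterations") = iter,
    Rcpp::Named("status") = status);
}

// Value and gradient of the smooth dual part, for reference evaluations.
// [[Rcpp::export(name = ".eb_dual_eval_cpp")]]
Rcpp::List eb_dual_eval_cpp(const arma::mat& Z, const arma::vec& cvec,
                            const arma::vec& theta) {
  const double n = static_cast<double>(Z.n_rows);
  vec eta = Z * theta;
  if (eta.max() > ETA_CAP) {
    return Rcpp::List::create(Rcpp::Named("value") = R_PosInf,
                              Rcpp::Named("gradient") = R_NilValue);
  }
  vec u = exp(eta);
  double f = mean(u) - dot(cvec, theta);
  vec g = Z.t() * u / n - cvec;
  return Rcpp::List::create(Rcpp::Named("value") = f,
                            Rcpp::Named("gradient") = g);
}
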