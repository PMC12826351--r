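#' Weighted ATE estimate
#'
#' The generalized average treatment effect estimate
#' `tau_hat = (1/n_s) sum_treated w_i Y_i - (1/n_s) sum_control w_i Y_i`.
#' Because each arm's weights average to 1 under the balancing
#' normalization, the two terms are weighted arm means and the estimate is
#' invariant to adding a constant to all outcomes.
#'
#' @param weights positive weight vector in subject order, normalized so
#'   each arm's weights average to 1 over n_s.
#' @param sample a [source_sample()].
#' @return An `ate_estimate`: `tau_hat`, `arm_means` (weighted treated and
#'   control means) and `effective_sample_sizes` (`(sum w)^2 / sum w^2` per
#'   arm, a plumbing diagnostic: small values explain wide intervals).
#' @export
weighted_ate <- function(weights, sample) {
  if (length(weights) != sample$n) {
    stop("weights and sample have different lengths")
  }
  n <- sample$n
  w1 <- weights[sample$S1]; w0 <- weights[sample$S0]
  m1 <- sum(w1 * sample$Y[sample$S1]) / n
  m0 <- sum(w0 * sample$Y[sample$S0]) / n
  structure(list(tau_hat = m1 - m0,
                 arm_means = c(treated = m1, control = m0),
                 effective_sample_sizes = c(
                   treated = sum(w1)^2 / sum(w1^2),
                   control = sum(w0)^2 / sum(w0^2))),
            class = "ate_estimate")
}

#' @export
print.ate_estimate <- function(x, ...) {
  cat(sprintf("<ate_estimate> tau_hat = %.4f (treated %.4f - control %.4f); ESS %.1f / %.1f\n",
              x$tau_hat, x$arm_means[1L], x$arm_means[2L],
              x$effective_sample_sizes[1L], x$effective_sample_sizes[2L]))
  invisible(x)
}
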