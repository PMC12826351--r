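# Fixtures built in code: random solvable balancing instances and drivers
# for the external convex-solver oracles.

# A random instance whose target moments are a mild exponential tilt of the
# source moments, hence interior to both arms' convex hulls (feasible).
make_instance <- function(n = 50, K_h = 3, K_g = 2, seed = 1,
                          tilt = 0.2) {
  set.seed(seed)
  p_cov <- K_h + K_g
  X <- matrix(rnorm(n * p_cov), n, p_cov,
              dimnames = list(NULL, paste0("x", seq_len(p_cov))))
  A <- c(rep(1L, ceiling(n / 2)), rep(0L, floor(n / 2)))
  Y <- rnorm(n)
  sample <- source_sample(X, A, Y)
  spec <- balance_spec(h = paste0("x", seq_len(K_h)),
                       g = if (K_g) paste0("x", K_h + seq_len(K_g)))
  H1 <- X[A == 1L, seq_len(K_h), drop = FALSE]
  tw <- exp(tilt * rnorm(nrow(H1)))
  vals <- as.numeric(crossprod(H1, tw) / sum(tw))
  names(vals) <- paste0("x", seq_len(K_h))
  summary <- target_summary(vals, setNames(rep(0.01, K_h), names(vals)),
                            n_t = 200)
  list(sample = sample, spec = spec, summary = summary,
       design = evaluate_spec(sample, spec))
}

run_py_oracle <- function(script, input) {
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)))
  jsonlite::write_json(input, fin, digits = NA, auto_unbox = TRUE)
  status <- system2("python", c(shQuote(test_path(script)), shQuote(fin),
                                shQuote(fout)),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout)) {
    stop("oracle script failed: ", paste(status, collapse = "\n"))
  }
  jsonlite::read_json(fout, simplifyVector = TRUE)
}

primal_oracle <- function(design, summary) {
  al <- ebtransport:::align_summary(summary, design$spec)
  run_py_oracle("oracle_primal.py",
                list(H1 = design$H1, H0 = design$H0,
                     G1 = design$G1, G0 = design$G0,
                     hbar = al$values, n = design$n))
}

approx_oracle <- function(design, summary, relaxation) {
  al <- ebtransport:::align_summary(summary, design$spec)
  p <- ncol(design$H); q <- ncol(design$G)
  rx <- ebtransport:::conform_relaxation(relaxation, p, q)
  Z <- ebtransport:::build_dual_design(design$H, design$G, design$A)
  run_py_oracle("oracle_approx.py",
                list(Z = Z, c = c(al$values, al$values, rep(0, q)),
                     delta = c(rx$delta1, rx$delta1_prime, rx$delta2)))
}

# entropy sum(w log w) of a weight vector
entropy_of <- function(w) sum(w * log(w))

# quick two-arm toy on the support {-1, 1}
toy_instance <- function(target = 0) {
  sample <- source_sample(
    matrix(c(-1, 1, -1, 1), ncol = 1, dimnames = list(NULL, "x")),
    c(1L, 1L, 0L, 0L), c(0, 0, 0, 0))
  spec <- balance_spec(h = "x")
  summary <- target_summary(c(x = target), c(x = 0), n_t = 50)
  list(sample = sample, spec = spec, summary = summary,
       design = evaluate_spec(sample, spec))
}
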