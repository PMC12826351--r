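Package: ebtransport
Title: Entropy-Balancing Generalization of Treatment Effects with
    Summary-Level Target Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generalizes an average treatment effect estimated from
    individual-level source data to a target population described only by
    moment summaries. Calibration weights are obtained by entropy balancing
    via its unconstrained exponential-family dual, with an L1-penalized
    relaxation when exact moment matching is infeasible. Confidence
    intervals are built by resampling-based perturbation: a nonparametric
    bootstrap of the source combined with a parametric Gaussian perturbation
    of the target moment vector (with approximate-balancing rescue of
    infeasible replicates). Includes a synthetic-data engine and a
    simulation driver for coverage, bias and infeasibility studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
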