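#' @useDynLib ebtransport, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor plogis pnorm quantile rbinom rnorm runif sd var setNames
#' @importFrom utils read.csv write.csv
NULL

#' Construct a source sample
#'
#' Bundles the individual-level data the method sees: a covariate matrix, a
#' binary treatment indicator and an outcome. The target population never
#' enters at the individual level; it is represented by [target_summary()].
#'
#' @param X numeric matrix or data frame of covariates (one row per subject);
#'   columns must be named, since balance specifications reference covariates
#'   by name.
#' @param A binary treatment vector (1 = treated).
#' @param Y numeric outcome vector.
#' @return An object of class `source_sample` with elements `X`, `A`, `Y`,
#'   `n`, and index vectors `S1` (treated) and `S0` (control).
#' @export
source_sample <- function(X, A, Y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  A <- as.integer(A)
  Y <- as.numeric(Y)
  n <- nrow(X)
  if (n < 2L) stop("source sample needs at least 2 subjects")
  if (length(A) != n || length(Y) != n) {
    stop("X, A and Y must have matching lengths")
  }
  if (anyNA(X) || anyNA(A) || anyNA(Y)) {
    stop("missing values are not allowed in the source sample")
  }
  if (!all(A %in% c(0L, 1L))) stop("A must be binary (0/1)")
  S1 <- which(A == 1L)
  S0 <- which(A == 0L)
  if (length(S1) == 0L || length(S0) == 0L) {
    stop("both treatment arms must be nonempty")
  }
  structure(list(X = X, A = A, Y = Y, n = n, S1 = S1, S0 = S0),
            class = "source_sample")
}

#' @export
print.source_sample <- function(x, ...) {
  cat(sprintf("<source_sample> n = %d (%d treated, %d control), %d covariates: %s\n",
              x$n, length(x$S1), length(x$S0), ncol(x$X),
              paste(colnames(x$X), collapse = ", ")))
  invisible(x)
}

#' Define a scalar moment function of the covariates
#'
#' A moment is a named scalar function of one or two covariate columns, the
#' building block of a balance specification. Supported transforms are
#' `identity` (first moment), `square` (second moment), `indicator(level)`
#' (category count for discrete covariates) and `product(col2)` (cross
#' moment).
#'
#' @param col covariate column name.
#' @param transform one of `"identity"`, `"square"`, `"indicator"`,
#'   `"product"`.
#' @param level level for the indicator transform.
#' @param col2 second column for the product transform.
#' @param name optional moment name; defaults to a descriptive one.
#' @return A `moment_def` object.
#' @export
moment_def <- function(col, transform = c("identity", "square", "indicator",
                                          "product"),
                       level = NULL, col2 = NULL, name = NULL) {
  transform <- match.arg(transform)
  if (transform == "indicator" && is.null(level)) {
    stop("indicator transform needs a `level`")
  }
  if (transform == "product" && is.null(col2)) {
    stop("product transform needs a `col2`")
  }
  if (is.null(name)) {
    name <- switch(transform,
                   identity = col,
                   square = paste0(col, "_sq"),
                   indicator = paste0(col, "_eq_", level),
                   product = paste0(col, "_x_", col2))
  }
  structure(list(name = name, col = col, transform = transform,
                 level = level, col2 = col2),
            class = "moment_def")
}

eval_moment <- function(def, X) {
  if (!def$col %in% colnames(X)) {
    stop(sprintf("moment '%s': column '%s' not found", def$name, def$col))
  }
  v <- X[, def$col]
  out <- switch(def$transform,
                identity = v,
                square = v^2,
                indicator = as.numeric(v == def$level),
                product = {
                  if (!def$col2 %in% colnames(X)) {
                    stop(sprintf("moment '%s': column '%s' not found",
                                 def$name, def$col2))
                  }
                  v * X[, def$col2]
                })
  bad <- which(!is.finite(out))
  if (length(bad)) {
    stop(sprintf("moment '%s' evaluates to a non-finite value at row %d",
                 def$name, bad[1L]))
  }
  out
}

as_moment_defs <- function(x) {
  if (inherits(x, "moment_def")) return(list(x))
  lapply(x, function(d) {
    if (inherits(d, "moment_def")) return(d)
    if (is.character(d) && length(d) == 1L) return(moment_def(d))
    stop("moments must be `moment_def` objects or column names")
  })
}

#' Construct a balance specification
#'
#' Names which covariate moments enter the two constraint sets of the
#' balancing problem: the H set matches each arm of the source sample to the
#' target's moment summaries (adjusting covariate shift), and the G set
#' equalizes moments between the two source arms (adjusting residual
#' confounding). The constant moment h0 = 1, which carries the per-arm
#' weight normalization, is always included implicitly.
#'
#' @param h list of [moment_def()]s (or bare column names, meaning first
#'   moments) for the shift-adjusting set; do not include the constant.
#' @param g list of [moment_def()]s or column names for the
#'   confounding-adjusting set; may be empty.
#' @return A `balance_spec` with elements `h` (including the constant as its
#'   first entry conceptually), `g`, `K_h`, `K_g`.
#' @export
balance_spec <- function(h, g = list()) {
  h <- as_moment_defs(h)
  g <- as_moment_defs(g)
  nm <- c("(intercept)", vapply(h, `[[`, "", "name"),
          vapply(g, `[[`, "", "name"))
  if (anyDuplicated(nm)) {
    stop("moment names must be unique across H and G")
  }
  structure(list(h = h, g = g, K_h = length(h), K_g = length(g),
                 h_names = vapply(h, `[[`, "", "name"),
                 g_names = vapply(g, `[[`, "", "name")),
            class = "balance_spec")
}

#' @export
print.balance_spec <- function(x, ...) {
  cat(sprintf("<balance_spec> H = (1, %s); G = (%s)\n",
              paste(x$h_names, collapse = ", "),
              if (x$K_g) paste(x$g_names, collapse = ", ") else ""))
  invisible(x)
}

#' Evaluate a balance specification on a source sample
#'
#' Builds the cached design matrices H and G evaluated on the treated and
#' control subjects, with the constant column first in H. Columns are checked
#' for finiteness and (jointly) for linear independence; a rank-deficient
#' design would make the balancing dual singular, so it fails here, loudly.
#'
#' @param sample a [source_sample()].
#' @param spec a [balance_spec()].
#' @return A `design_matrices` object with `H1`, `H0`, `G1`, `G0` (arm-wise
#'   evaluations), the full-sample `H`, `G`, the treatment vector and arm
#'   index sets.
#' @export
evaluate_spec <- function(sample, spec) {
  stopifnot(inherits(sample, "source_sample"), inherits(spec, "balance_spec"))
  X <- sample$X
  H <- cbind(`(intercept)` = rep(1, sample$n))
  for (d in spec$h) H <- cbind(H, eval_moment(d, X))
  colnames(H) <- c("(intercept)", spec$h_names)
  G <- matrix(0, sample$n, 0)
  if (spec$K_g) {
    G <- do.call(cbind, lapply(spec$g, function(d) eval_moment(d, X)))
    colnames(G) <- spec$g_names
  }
  check_design_rank(H, G)
  structure(list(H1 = H[sample$S1, , drop = FALSE],
                 H0 = H[sample$S0, , drop = FALSE],
                 G1 = G[sample$S1, , drop = FALSE],
                 G0 = G[sample$S0, , drop = FALSE],
                 H = H, G = G, A = sample$A,
                 S1 = sample$S1, S0 = sample$S0, n = sample$n,
                 spec = spec),
            class = "design_matrices")
}

# Collinear balance columns give a singular dual Hessian; flag them before
# any solve. Tolerance: singular values below 1e-8 x largest.
check_design_rank <- function(H, G, tol = 1e-8) {
  M <- cbind(H[, -1L, drop = FALSE], G)
  if (ncol(M) == 0L) return(invisible(TRUE))
  # center: collinearity with the constant column counts too
  M <- sweep(M, 2L, colMeans(M))
  sv <- svd(cbind(1, M), nu = 0, nv = 0)$d
  if (min(sv) < tol * max(sv)) {
    stop("balance columns are collinear on the source sample ",
         "(rank-deficient design)")
  }
  invisible(TRUE)
}

#' Construct a target summary
#'
#' The entire footprint of the target sample: the values of the moment
#' functions averaged over the target sample, the sampling variances of
#' those averages, and the target sample size. The variances are variances
#' of the *sample means* (column variance divided by the target sample
#' size), not of the underlying covariates — they parameterize the Gaussian
#' perturbation used for interval construction. For binary/discrete moments
#' an omitted variance is auto-filled as `v (1 - v) / n_t`.
#'
#' @param values named numeric vector of target moment values (the constant
#'   moment is added automatically).
#' @param variances named numeric vector of sampling variances of `values`;
#'   entries may be omitted only for moments flagged in `binary`.
#' @param n_t target sample size.
#' @param covariance optional full covariance matrix of the moment vector
#'   (same names as `values`); when present it takes precedence over
#'   `variances` + source-estimated correlation.
#' @param binary character vector naming binary moments whose variance may
#'   be auto-filled.
#' @return A `target_summary` with the constant moment in first position.
#' @export
target_summary <- function(values, variances = NULL, n_t,
                           covariance = NULL, binary = character()) {
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("target moment values must be named")
  }
  values <- values[names(values) != "(intercept)"]
  nm <- names(values)
  n_t <- as.integer(n_t)
  if (is.na(n_t) || n_t < 1L) stop("n_t must be a positive integer")
  vr <- setNames(rep(NA_real_, length(values)), nm)
  if (is.null(variances) && !is.null(covariance)) {
    cv <- as.matrix(covariance)
    variances <- setNames(diag(cv), if (is.null(rownames(cv))) nm
                          else rownames(cv))
  }
  if (!is.null(variances)) {
    if (is.null(names(variances))) stop("variances must be named")
    unknown <- setdiff(names(variances), nm)
    if (length(unknown)) {
      stop("variances given for unknown moments: ",
           paste(unknown, collapse = ", "))
    }
    vr[names(variances)] <- as.numeric(variances)
  }
  miss <- nm[is.na(vr)]
  fillable <- intersect(miss, binary)
  for (b in fillable) vr[b] <- values[b] * (1 - values[b]) / n_t
  miss <- nm[is.na(vr)]
  if (length(miss)) {
    stop("variance of the target sample mean is missing for continuous ",
         "moment(s) ", paste(miss, collapse = ", "),
         ": the resampling-perturbation CI requires var(Hbar_T) ",
         "(binary moments may omit it)")
  }
  if (any(vr < 0)) stop("variances must be nonnegative")
  full_values <- c(`(intercept)` = 1, values)
  full_var <- c(`(intercept)` = 0, vr)
  if (!is.null(covariance)) {
    covariance <- as.matrix(covariance)
    if (is.null(rownames(covariance))) {
      if (nrow(covariance) != length(values)) {
        stop("covariance dimension does not match the moment values")
      }
      dimnames(covariance) <- list(nm, nm)
    }
    covariance <- covariance[nm, nm, drop = FALSE]
    if (max(abs(covariance - t(covariance))) > 1e-8) {
      stop("covariance must be symmetric")
    }
    full_cov <- matrix(0, length(nm) + 1L, length(nm) + 1L,
                       dimnames = list(names(full_values), names(full_values)))
    full_cov[-1L, -1L] <- (covariance + t(covariance)) / 2
    ev <- eigen(full_cov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10) stop("covariance is not positive semidefinite")
    covariance <- full_cov
  }
  structure(list(values = full_values, variances = full_var,
                 covariance = covariance, n_t = n_t),
            class = "target_summary")
}

#' @export
print.target_summary <- function(x, ...) {
  cat(sprintf("<target_summary> n_t = %d\n", x$n_t))
  print(data.frame(value = x$values, variance = x$variances))
  invisible(x)
}

# Reorder the summary to a spec's H ordering; errors on missing moments.
align_summary <- function(summary, spec) {
  nm <- c("(intercept)", spec$h_names)
  miss <- setdiff(nm, names(summary$values))
  if (length(miss)) {
    stop("target summary lacks moment(s) required by the balance spec: ",
         paste(miss, collapse = ", "))
  }
  list(values = unname(summary$values[nm]),
       variances = unname(summary$variances[nm]),
       covariance = if (!is.null(summary$covariance))
         unname(summary$covariance[nm, nm, drop = FALSE]),
       n_t = summary$n_t, names = nm)
}

#' Read a source sample from CSV
#'
#' Expects a header row, a binary column `A`, a numeric column `Y`, and any
#' number of covariate columns.
#'
#' @param path file path.
#' @return A [source_sample()].
#' @export
read_source <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  need <- c("A", "Y")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("source file is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  covars <- setdiff(names(df), need)
  if (!length(covars)) stop("source file has no covariate columns")
  source_sample(df[covars], df$A, df$Y)
}

#' Write a source sample to CSV
#' @param sample a [source_sample()].
#' @param path file path.
#' @export
write_source <- function(sample, path) {
  df <- data.frame(sample$X, A = sample$A, Y = sample$Y,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a target summary (and its moment definitions) from JSON or YAML
#'
#' The schema is a mapping with keys `n_t`, `moments` (a list of entries
#' `name`, `definition` (`col`, `transform`, optional `level`/`col2`),
#' `value`, optional `variance`, optional `binary` flag) and an optional
#' `covariance` matrix. The moment definitions are attached as the
#' `"definitions"` attribute so a balance spec can be built with
#' [spec_from_target()].
#'
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return A [target_summary()] with attribute `definitions`.
#' @export
read_target_summary <- function(path) {
  ext <- tolower(tools::file_ext(path))
  obj <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  for (key in c("n_t", "moments")) {
    if (is.null(obj[[key]])) {
      stop("target summary file is missing required key '", key, "'")
    }
  }
  defs <- list(); vals <- c(); vars <- c(); binary <- character()
  for (m in obj$moments) {
    if (is.null(m$name) || is.null(m$value)) {
      stop("each moment needs 'name' and 'value' keys")
    }
    d <- m$definition
    if (is.null(d) || is.null(d$col)) {
      stop("moment '", m$name, "' is missing its 'definition' (col, transform)")
    }
    defs[[m$name]] <- moment_def(d$col,
                                 transform = if (is.null(d$transform))
                                   "identity" else d$transform,
                                 level = d$level, col2 = d$col2,
                                 name = m$name)
    vals[m$name] <- as.numeric(m$value)
    if (!is.null(m$variance)) vars[m$name] <- as.numeric(m$variance)
    if (isTRUE(m$binary)) binary <- c(binary, m$name)
  }
  covm <- NULL
  if (!is.null(obj$covariance)) {
    covm <- do.call(rbind, lapply(obj$covariance, unlist))
    dimnames(covm) <- list(names(vals), names(vals))
  }
  ts <- target_summary(vals, variances = if (length(vars)) vars,
                       n_t = obj$n_t, covariance = covm, binary = binary)
  attr(ts, "definitions") <- defs
  ts
}

#' Write a target summary to JSON
#' @param summary a [target_summary()]; if it carries a `definitions`
#'   attribute (or `spec` is given) the moment definitions are embedded.
#' @param path output path.
#' @param spec optional [balance_spec()] supplying the moment definitions.
#' @param binary character vector of moments to flag as binary.
#' @export
write_target_summary <- function(summary, path, spec = NULL,
                                 binary = character()) {
  defs <- attr(summary, "definitions")
  if (is.null(defs) && !is.null(spec)) {
    defs <- setNames(spec$h, spec$h_names)
  }
  nm <- setdiff(names(summary$values), "(intercept)")
  moments <- lapply(nm, function(k) {
    d <- defs[[k]]
    def <- if (is.null(d)) list(col = k, transform = "identity") else {
      out <- list(col = d$col, transform = d$transform)
      if (!is.null(d$level)) out$level <- d$level
      if (!is.null(d$col2)) out$col2 <- d$col2
      out
    }
    entry <- list(name = k, definition = def,
                  value = unname(summary$values[k]),
                  variance = unname(summary$variances[k]))
    if (k %in% binary) entry$binary <- TRUE
    entry
  })
  obj <- list(n_t = summary$n_t, moments = moments)
  if (!is.null(summary$covariance)) {
    obj$covariance <- apply(summary$covariance[-1L, -1L, drop = FALSE], 1L,
                            as.list, simplify = FALSE)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Build a balance spec from a target summary's moment definitions
#' @param summary a [read_target_summary()] result.
#' @param g confounding-adjusting moments ([moment_def()]s or column names).
#' @return A [balance_spec()].
#' @export
spec_from_target <- function(summary, g = list()) {
  defs <- attr(summary, "definitions")
  if (is.null(defs)) stop("summary carries no moment definitions")
  balance_spec(h = unname(defs), g = g)
}

#' Write an analysis result to JSON
#'
#' @param path output path.
#' @param estimate an ATE estimate (from [weighted_ate()]) or a number.
#' @param interval optional CI result (from [rpm_ci()]/[rpm_ab_ci()]).
#' @param diagnostics optional named list of extra diagnostics.
#' @export
write_results <- function(path, estimate, interval = NULL,
                          diagnostics = NULL) {
  out <- list()
  if (inherits(estimate, "ate_estimate")) {
    out$estimate <- estimate$tau_hat
    out$arm_means <- as.list(estimate$arm_means)
    out$effective_sample_sizes <- as.list(estimate$effective_sample_sizes)
  } else {
    out$estimate <- as.numeric(estimate)
  }
  if (!is.null(interval)) {
    out$ci <- list(lower = interval$lower, upper = interval$upper,
                   method = interval$method,
                   B_requested = interval$B_requested,
                   B_used = interval$B_used,
                   infeasible_count = interval$infeasible_count)
  }
  if (!is.null(diagnostics)) out$diagnostics <- diagnostics
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
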