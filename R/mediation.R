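#' Single-level mediation with bootstrap inference
#'
#' Decomposes the total effect of X on Y (path c) into a direct effect
#' (path c') and an indirect effect through the mediator M (path ab):
#' a from regressing M on X; b and c' from regressing Y on M and X jointly
#' (b is thereby controlled for X); c from regressing Y on X. For OLS,
#' `ab + c' = c` exactly. Standard errors and two-tailed p-values come from
#' a percentile bootstrap over participants.
#'
#' @param X,M,Y Per-participant vectors (equal length >= 5, finite).
#' @param n_boot Bootstrap resamples (default 10,000).
#' @param seed Integer seed for the bootstrap.
#' @param standardize Z-score X, M and Y before estimation (default `TRUE`).
#' @return Object of class `mediation_result`: data frame `paths` with
#'   point estimates, bootstrap SEs and p-values for a, b, c, c_prime, ab;
#'   plus `n`, `n_boot`, `seed`, `standardize`.
#' @export
mediate <- function(X, M, Y, n_boot = 10000L, seed = 1, standardize = TRUE) {
  n <- length(X)
  stopifnot(length(M) == n, length(Y) == n, n >= 5,
            all(is.finite(X)), all(is.finite(M)), all(is.finite(Y)))
  if (stats::sd(X) < 1e-12 || stats::sd(M) < 1e-12) {
    stop("mediate: X and M must have non-zero variance")
  }
  if (standardize) {
    X <- as.numeric(scale(X)); M <- as.numeric(scale(M)); Y <- as.numeric(scale(Y))
  }
  paths <- function(idx) {
    x <- X[idx]; m <- M[idx]; y <- Y[idx]
    if (stats::sd(x) < 1e-12 || stats::sd(m) < 1e-12) return(rep(NA_real_, 5))
    a <- stats::lm.fit(cbind(1, x), m)$coefficients[2]
    bc <- stats::lm.fit(cbind(1, m, x), y)$coefficients
    # exact collinearity (e.g. M identical to X) drops a column; the
    # dropped coefficient contributes nothing
    bc[is.na(bc)] <- 0
    b <- bc[2]; cprime <- bc[3]
    cc <- stats::lm.fit(cbind(1, x), y)$coefficients[2]
    c(a = unname(a), b = unname(b), c = unname(cc),
      c_prime = unname(cprime), ab = unname(a * b))
  }
  est <- paths(seq_len(n))
  boot <- with_seed(seed, {
    t(vapply(seq_len(n_boot),
             function(i) paths(sample.int(n, n, replace = TRUE)),
             numeric(5)))
  })
  boot <- boot[stats::complete.cases(boot), , drop = FALSE]
  se <- apply(boot, 2, stats::sd)
  pval <- apply(boot, 2, function(b) {
    lo <- mean(b < 0) + 0.5 * mean(b == 0)
    2 * min(lo, 1 - lo)
  })
  structure(list(paths = data.frame(path = names(est), estimate = unname(est),
                                    se = unname(se), p = unname(pval),
                                    row.names = NULL),
                 n = n, n_boot = nrow(boot), seed = seed,
                 standardize = standardize),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, digits = 3, ...) {
  cat("Single-level mediation (n = ", x$n, ", ", x$n_boot,
      " bootstrap resamples", if (x$standardize) ", standardized", ")\n",
      sep = "")
  print(cbind(x$paths[1], round(x$paths[-1], digits)), row.names = FALSE)
  invisible(x)
}
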