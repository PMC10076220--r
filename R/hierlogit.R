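# Penalized-Newton logistic fits and a two-stage empirical-Bayes
# hierarchical logistic model. This is the fast engine behind grid search,
# leave-one-trial-out CV and the weight analyses; lme4::glmer is the
# reference engine for the headline single-predictor fit.

# Bernoulli log-likelihood, numerically stable
bernoulli_ll <- function(eta, y) {
  sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
}

#' Penalized Newton logistic regression
#'
#' Maximises the Bernoulli log-likelihood plus an independent Gaussian
#' log-prior on the coefficients (ridge toward `prior_mean` with precision
#' `prior_prec`). A tiny default ridge keeps separated fits finite.
#'
#' @param X Design matrix.
#' @param y 0/1 response.
#' @param offset Linear-predictor offset.
#' @param prior_mean,prior_prec Gaussian prior center and precision per
#'   coefficient.
#' @param init Starting coefficients.
#' @return List: `coef`, `loglik` (unpenalized), `hess` (penalized), and
#'   `converged`.
#' @keywords internal
logit_newton <- function(X, y, offset = 0, prior_mean = NULL, prior_prec = NULL,
                         init = NULL, maxit = 50L, tol = 1e-9) {
  X <- as.matrix(X)
  p <- ncol(X)
  beta <- init %||% rep(0, p)
  pm <- prior_mean %||% rep(0, p)
  pp <- prior_prec %||% rep(1e-8, p)
  converged <- FALSE
  H <- diag(p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta) + offset
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    g <- drop(crossprod(X, y - mu)) - pp * (beta - pm)
    H <- crossprod(X * w, X)
    diag(H) <- diag(H) + pp
    delta <- tryCatch(solve(H, g), error = function(e) rep(0, p))
    # dampen huge steps (separation)
    if (max(abs(delta)) > 10) delta <- delta * 10 / max(abs(delta))
    beta <- beta + delta
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  list(coef = beta, loglik = bernoulli_ll(drop(X %*% beta) + offset, y),
       hess = H, converged = converged)
}

#' Two-stage empirical-Bayes hierarchical logistic regression
#'
#' Fits `logit P(y = 1) = beta0 + sum_j (beta_j + b_pj) x_j` with
#' participant-level deviations `b_pj ~ N(0, tau_j^2)` by alternating
#' (i) penalized per-participant Newton fits of the total coefficients
#' `theta_pj = beta_j + b_pj` shrunk toward the population coefficients and
#' (ii) moment/EM updates of `beta`, `tau^2`, and the shared intercept.
#'
#' @param X Predictor matrix (participant-varying columns; no intercept —
#'   a shared intercept is always included and never varies by participant).
#' @param y 0/1 response.
#' @param participant Participant id per row.
#' @param n_iter Outer iterations.
#' @return List of class `hier_logit`: `intercept`, `fixed` (population
#'   slopes), `tau2`, `coef` (participants x predictors total coefficients),
#'   `participants`, `loglik` (conditional, at the participant coefficients),
#'   plus the per-participant posterior variances `coef_var`.
#' @export
hier_logistic <- function(X, y, participant, n_iter = 8L) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  y <- as.numeric(y)
  pid <- as.character(participant)
  ids <- unique(pid)
  rows <- split(seq_along(y), factor(pid, levels = ids))

  # degenerate predictors: no information to estimate a slope
  degenerate <- apply(X, 2, stats::sd) < 1e-12
  if (any(degenerate)) {
    warning("hier_logistic: degenerate (constant) predictor(s): ",
            paste(colnames(X)[degenerate], collapse = ", "))
  }

  pooled <- logit_newton(cbind(1, X), y)
  beta0 <- pooled$coef[1]
  beta <- pooled$coef[-1]
  tau2 <- rep(1, p)
  theta <- matrix(rep(beta, each = length(ids)), length(ids), p,
                  dimnames = list(ids, colnames(X)))
  V <- matrix(1, length(ids), p)

  for (it in seq_len(n_iter)) {
    for (k in seq_along(ids)) {
      r <- rows[[k]]
      f <- logit_newton(X[r, , drop = FALSE], y[r], offset = beta0,
                        prior_mean = beta, prior_prec = 1 / tau2,
                        init = theta[k, ])
      theta[k, ] <- f$coef
      V[k, ] <- diag(solve(f$hess))
    }
    beta <- colMeans(theta)
    tau2 <- pmin(pmax(colMeans(sweep(theta, 2, beta)^2) + colMeans(V), 1e-4), 25)
    tau2[degenerate] <- 1e-4
    # refit the shared intercept given the participant slopes
    off <- rowSums(X * theta[match(pid, ids), , drop = FALSE])
    beta0 <- logit_newton(matrix(1, length(y), 1), y, offset = off,
                          init = beta0)$coef[1]
  }
  eta <- beta0 + rowSums(X * theta[match(pid, ids), , drop = FALSE])
  structure(list(intercept = beta0, fixed = beta, tau2 = tau2, coef = theta,
                 coef_var = V, participants = ids,
                 loglik = bernoulli_ll(eta, y), degenerate = degenerate),
            class = "hier_logit")
}

#' Per-trial leave-one-out log-likelihoods for a hierarchical logistic fit
#'
#' For each trial, refits the held-out participant's coefficients on their
#' remaining trials — keeping the population shrinkage target (`fixed`,
#' `tau2`) and the shared intercept at their full-data values — and scores
#' the held-out choice.
#'
#' @param fit A [hier_logistic()] fit.
#' @inheritParams hier_logistic
#' @return Numeric vector of held-out log-likelihoods, one per row of `X`.
#' @export
hier_loo <- function(fit, X, y, participant) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  pid <- as.character(participant)
  out <- numeric(length(y))
  for (k in seq_along(fit$participants)) {
    id <- fit$participants[k]
    r <- which(pid == id)
    Xp <- X[r, , drop = FALSE]
    yp <- y[r]
    for (j in seq_along(r)) {
      f <- logit_newton(Xp[-j, , drop = FALSE], yp[-j], offset = fit$intercept,
                        prior_mean = fit$fixed, prior_prec = 1 / fit$tau2,
                        init = fit$coef[k, ], maxit = 25L, tol = 1e-8)
      eta <- fit$intercept + sum(Xp[j, ] * f$coef)
      out[r[j]] <- bernoulli_ll(eta, yp[j])
    }
  }
  out
}
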