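#' Random-effects Bayesian model selection
#'
#' Variational treatment of model frequencies in the population: model
#' attributions are latent, the frequency vector has a Dirichlet prior
#' (`alpha0` per model), and the posterior Dirichlet is found by iterating
#' attribution responsibilities against digamma-corrected evidences.
#' Exceedance probabilities — the probability that each model is more
#' frequent than all competitors — are estimated by Monte-Carlo sampling of
#' the posterior Dirichlet.
#'
#' @param evidence Participants x models matrix of log model evidences
#'   (here: summed per-participant LOO-CV log-likelihoods).
#' @param alpha0 Dirichlet prior count per model (default 1, uniform).
#' @param n_samples Dirichlet Monte-Carlo draws for the exceedance
#'   probabilities (default 1e5).
#' @param seed Seed for the Monte-Carlo.
#' @param tol,maxit Convergence control for the variational loop.
#' @return Object of class `model_comparison`: `frequency` (expected
#'   posterior model frequencies, a simplex), `frequency_sd`, `xp`
#'   (exceedance probabilities), `alpha` (posterior Dirichlet counts),
#'   `attribution` (participants x models responsibility matrix).
#' @export
bms <- function(evidence, alpha0 = 1, n_samples = 1e5, seed = 1,
                tol = 1e-8, maxit = 500L) {
  evidence <- as.matrix(evidence)
  stopifnot(all(is.finite(evidence)), ncol(evidence) >= 2)
  n <- nrow(evidence); k <- ncol(evidence)
  alpha <- rep(alpha0, k)
  for (it in seq_len(maxit)) {
    alpha_prev <- alpha
    lw <- sweep(evidence, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    lw <- lw - apply(lw, 1, max)
    u <- exp(lw)
    u <- u / rowSums(u)
    alpha <- alpha0 + colSums(u)
    if (max(abs(alpha - alpha_prev)) < tol) break
  }
  freq <- alpha / sum(alpha)
  a0 <- sum(alpha)
  freq_sd <- sqrt(alpha * (a0 - alpha) / (a0^2 * (a0 + 1)))
  xp <- with_seed(seed, {
    g <- matrix(stats::rgamma(n_samples * k, shape = rep(alpha, each = n_samples)),
                n_samples, k)
    tabulate(max.col(g), k) / n_samples
  })
  structure(list(frequency = stats::setNames(freq, colnames(evidence)),
                 frequency_sd = stats::setNames(freq_sd, colnames(evidence)),
                 xp = stats::setNames(xp, colnames(evidence)),
                 alpha = stats::setNames(alpha, colnames(evidence)),
                 attribution = u, n_participants = n),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, digits = 3, ...) {
  cat("Random-effects model comparison (", x$n_participants,
      " participants)\n", sep = "")
  print(round(rbind(frequency = x$frequency, sd = x$frequency_sd,
                    exceedance = x$xp), digits))
  invisible(x)
}
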