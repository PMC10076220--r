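#' GP posterior mean over all stimuli
#'
#' Conditions a zero-mean Gaussian process with kernel `K` on observed
#' (stimulus, reward) pairs and returns the posterior mean for every
#' stimulus: `m = K[, s] (K[s, s] + sigma2 I)^-1 y`. Repeated observations
#' of the same stimulus enter as separate rows; the observation noise
#' `sigma2` handles duplicates naturally.
#'
#' @param K n x n kernel matrix.
#' @param obs_s Integer vector of observed stimulus ids.
#' @param obs_y Numeric vector of observed (centered) rewards.
#' @param sigma2 Observation noise variance; default 0.01.
#' @return Numeric n-vector of posterior means (zeros with no observations).
#' @export
gp_posterior_mean <- function(K, obs_s, obs_y, sigma2 = 0.01) {
  stopifnot(sigma2 > 0, length(obs_s) == length(obs_y))
  n <- nrow(K)
  if (length(obs_s) == 0) return(numeric(n))
  Ko <- K[obs_s, obs_s, drop = FALSE] + sigma2 * diag(length(obs_s))
  ks <- K[, obs_s, drop = FALSE]
  drop(ks %*% solve(Ko, obs_y))
}

#' Log marginal likelihood of rewards under a GP
#'
#' Evidence of the zero-mean Gaussian model `y ~ N(0, K[s, s] + sigma2 I)`.
#' @inheritParams gp_posterior_mean
#' @export
gp_log_marginal <- function(K, obs_s, obs_y, sigma2 = 0.01) {
  m <- length(obs_s)
  if (m == 0) return(0)
  S <- K[obs_s, obs_s, drop = FALSE] + sigma2 * diag(m)
  ch <- chol(S)
  z <- backsolve(ch, obs_y, transpose = TRUE)
  -0.5 * sum(z^2) - sum(log(diag(ch))) - 0.5 * m * log(2 * pi)
}

#' Sequential context-conditioned GP predictions for a choice dataset
#'
#' For every trial, predicts the reward of both presented options from a GP
#' conditioned on all (stimulus, reward) pairs observed *so far in the same
#' context*; after the choice, the chosen stimulus' reward joins that
#' context's observations. Rewards are mean-centered per context by the
#' running mean of that context's observations before conditioning (the GP
#' prior mean is 0); predictions are reported back on the raw reward scale.
#'
#' The per-trial solve reuses an incrementally updated Cholesky factor of
#' the growing observation covariance, so a full run is O(sum t^2).
#'
#' @param K n x n kernel matrix.
#' @param dataset Choice data frame with columns `trial`, `context`,
#'   `option_a`, `option_b`, `chosen` (`"a"`/`"b"`), `reward`.
#' @param sigma2 Observation noise variance.
#' @param center `"context"` (default): center rewards by the running
#'   per-context mean; `"global"`: by the running overall mean; `"none"`.
#' @return Data frame with per-trial `pred_a`, `pred_b`, `pred_diff`
#'   (`pred_a - pred_b`), `pred_chosen`, `pred_unchosen`, and the centering
#'   constant `center_const` in effect at prediction time. Predictions are
#'   on the raw reward scale; `pred_diff` is centering-invariant.
#' @export
sequential_predictions <- function(K, dataset, sigma2 = 0.01,
                                   center = c("context", "global", "none")) {
  center <- match.arg(center)
  stopifnot(sigma2 > 0)
  K <- unclass(as.matrix(K))
  n <- nrow(K)
  nt <- nrow(dataset)
  ctx <- match(dataset$context, sort(unique(dataset$context)))
  opt_a <- dataset$option_a
  opt_b <- dataset$option_b
  chose_a <- dataset$chosen == "a"
  reward <- dataset$reward
  nctx <- max(ctx)
  nt_ctx <- tabulate(ctx, nctx)
  # per-context growing state, preallocated: stimulus ids, rewards, the
  # inverse of K[obs, obs] + sigma2 I grown in place by bordered-inverse
  # updates, and incrementally maintained Kinv %*% y and Kinv %*% 1 (so the
  # posterior-mean weights alpha = Kinv (y - mu) are two stored vectors)
  obs_s <- lapply(nt_ctx, function(m) integer(m))
  obs_y <- iv_y <- iv_1 <- lapply(nt_ctx, function(m) numeric(m))
  Ki_ctx <- lapply(nt_ctx, function(m) matrix(0, m, m))
  m_ctx <- integer(nctx)
  pred_a <- pred_b <- pred_ch <- pred_un <- cent <- numeric(nt)
  n_all <- 0L; sum_all <- 0
  sum_ctx <- numeric(nctx)
  for (i in seq_len(nt)) {
    cc <- ctx[i]
    m <- m_ctx[cc]
    mu <- switch(center,
                 context = if (m > 0) sum_ctx[cc] / m else 0,
                 global = if (n_all > 0) sum_all / n_all else 0,
                 none = 0)
    a <- opt_a[i]; b <- opt_b[i]
    if (m == 0) {
      pa <- pb <- mu
    } else {
      s <- obs_s[[cc]][seq_len(m)]
      alpha <- iv_y[[cc]][seq_len(m)] - mu * iv_1[[cc]][seq_len(m)]
      pa <- sum(K[a, s] * alpha) + mu
      pb <- sum(K[b, s] * alpha) + mu
    }
    pred_a[i] <- pa; pred_b[i] <- pb; cent[i] <- mu
    pred_ch[i] <- if (chose_a[i]) pa else pb
    pred_un[i] <- if (chose_a[i]) pb else pa
    # append the experienced outcome to this context's observations
    s_new <- if (chose_a[i]) a else b
    y_new <- reward[i]
    kss <- K[s_new, s_new] + sigma2
    if (m == 0) {
      d <- 1 / kss
      Ki_ctx[[cc]][1, 1] <- d
      iv_y[[cc]][1] <- d * y_new
      iv_1[[cc]][1] <- d
    } else {
      idx <- seq_len(m)
      k_vec <- K[obs_s[[cc]][idx], s_new]
      u <- drop(Ki_ctx[[cc]][idx, idx, drop = FALSE] %*% k_vec)
      d <- 1 / max(kss - sum(k_vec * u), 1e-12)
      Ki_ctx[[cc]][idx, idx] <- Ki_ctx[[cc]][idx, idx, drop = FALSE] +
        d * tcrossprod(u)
      Ki_ctx[[cc]][idx, m + 1L] <- -d * u
      Ki_ctx[[cc]][m + 1L, idx] <- -d * u
      Ki_ctx[[cc]][m + 1L, m + 1L] <- d
      ry <- d * (y_new - sum(u * obs_y[[cc]][idx]))
      iv_y[[cc]][idx] <- iv_y[[cc]][idx] - ry * u
      iv_y[[cc]][m + 1L] <- ry
      r1 <- d * (1 - sum(u * rep(1, m)))
      iv_1[[cc]][idx] <- iv_1[[cc]][idx] - r1 * u
      iv_1[[cc]][m + 1L] <- r1
    }
    m_ctx[cc] <- m + 1L
    obs_s[[cc]][m + 1L] <- s_new
    obs_y[[cc]][m + 1L] <- y_new
    sum_ctx[cc] <- sum_ctx[cc] + y_new
    n_all <- n_all + 1L; sum_all <- sum_all + y_new
  }
  data.frame(trial = dataset$trial, context = dataset$context,
             option_a = opt_a, option_b = opt_b,
             pred_a = pred_a, pred_b = pred_b, pred_diff = pred_a - pred_b,
             pred_chosen = pred_ch, pred_unchosen = pred_un,
             center_const = cent)
}

#' Posterior probability that the spatial map generated the rewards
#'
#' Compares the GP marginal likelihoods of all rewards observed through
#' trial `t` (per context, mean-centered) under the spatial and the
#' predictive kernel, combined with a uniform model prior.
#'
#' @param dataset Choice data frame (see [sequential_predictions()]).
#' @param K_spatial,K_predictive Kernel matrices with fitted hyperparameters.
#' @param t Trial index; `t = 0` returns the prior 0.5.
#' @param sigma2 Observation noise variance.
#' @return `P(spatial | rewards through t)`.
#' @export
map_posterior_probability <- function(dataset, K_spatial, K_predictive, t,
                                      sigma2 = 0.01) {
  if (t <= 0) return(0.5)
  sub <- dataset[seq_len(min(t, nrow(dataset))), ]
  lev <- function(K) {
    tot <- 0
    for (cc in unique(sub$context)) {
      d <- sub[sub$context == cc, ]
      s <- ifelse(d$chosen == "a", d$option_a, d$option_b)
      y <- d$reward - mean(d$reward)
      tot <- tot + gp_log_marginal(K, s, y, sigma2)
    }
    tot
  }
  dl <- lev(K_spatial) - lev(K_predictive)
  1 / (1 + exp(-dl))
}
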