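# independent oracle for the GP posterior mean: ridge regression in kernel
# space solved by eigendecomposition (different factorization from the
# implementation's direct solve / bordered-inverse updates)
gp_mean_oracle <- function(K, s, y, sigma2) {
  if (length(s) == 0) return(numeric(nrow(K)))
  Ko <- K[s, s, drop = FALSE] + sigma2 * diag(length(s))
  eg <- eigen((Ko + t(Ko)) / 2, symmetric = TRUE)
  alpha <- eg$vectors %*% ((t(eg$vectors) %*% y) / eg$values)
  drop(K[, s, drop = FALSE] %*% alpha)
}

random_psd_kernel <- function(n, seed) {
  set.seed(seed)
  P <- matrix(runif(2 * n, -8, 8), n, 2)
  gaussian_kernel(euclidean_distances(P), lambda = runif(1, 1, 6))
}

test_that("GP posterior mean: closed-form scalar case and prior behavior", {
  K <- identity_kernel(5)
  m <- gp_posterior_mean(K, obs_s = 2, obs_y = 3, sigma2 = 0.01)
  expect_equal(m[2], 3 / 1.01)
  expect_equal(m[-2], rep(0, 4))
  expect_equal(gp_posterior_mean(K, integer(0), numeric(0)), rep(0, 5))
})

test_that("GP posterior mean matches the spectral ridge oracle", {
  for (seed in 1:8) {
    K <- unclass(random_psd_kernel(10, seed))
    set.seed(seed + 100)
    s <- sample.int(10, 15, replace = TRUE)
    y <- rnorm(15, 0, 10)
    expect_lt(max(abs(gp_posterior_mean(K, s, y, 0.01) -
                        gp_mean_oracle(K, s, y, 0.01))), 1e-8)
  }
})

test_that("near-interpolation for strictly PD kernels as noise vanishes", {
  K <- unclass(random_psd_kernel(8, 3)) + 1e-6 * diag(8)
  set.seed(3)
  s <- sample.int(8, 6)
  y <- rnorm(6, 0, 5)
  m <- gp_posterior_mean(K, s, y, sigma2 = 1e-10)
  expect_equal(m[s], y, tolerance = 1e-4)
})

test_that("sequential predictions equal from-scratch batch refits per trial", {
  lay <- fixture_layout()
  ctxs <- fixture_contexts(lay)
  for (seed in 1:6) {
    K <- unclass(random_psd_kernel(12, seed + 20))
    d <- simulate_choices(K, ctxs, temperature = 5, seed = seed)
    sp <- sequential_predictions(K, d)
    for (i in c(1, 2, 11, 37, 100)) {
      prev <- d[seq_len(i - 1), , drop = FALSE]
      prev <- prev[prev$context == d$context[i], , drop = FALSE]
      s <- ifelse(prev$chosen == "a", prev$option_a, prev$option_b)
      mu <- if (nrow(prev)) mean(prev$reward) else 0
      m <- gp_mean_oracle(K, s, prev$reward - mu, 0.01) + mu
      expect_lt(abs(sp$pred_diff[i] - (m[d$option_a[i]] - m[d$option_b[i]])),
                1e-8)
      expect_lt(abs(sp$pred_a[i] - m[d$option_a[i]]), 1e-8)
    }
    # first trial of each context has no observations: prior prediction
    expect_equal(sp$pred_diff[1], 0)
    expect_equal(sp$pred_diff[11], 0)
  }
})

test_that("context firewall: the other context's rewards never leak", {
  lay <- fixture_layout()
  ctxs <- fixture_contexts(lay)
  K <- unclass(random_psd_kernel(12, 7))
  d <- simulate_choices(K, ctxs, temperature = 5, seed = 9)
  sp <- sequential_predictions(K, d)
  # permute context-2 rewards: context-1 predictions must be unchanged
  d2 <- d
  r2 <- which(d2$context == 2)
  set.seed(1)
  d2$reward[r2] <- d2$reward[sample(r2)]
  sp2 <- sequential_predictions(K, d2)
  r1 <- which(d$context == 1)
  expect_identical(sp$pred_diff[r1], sp2$pred_diff[r1])
  # identity kernel: a single observation only moves its own stimulus
  K_id <- identity_kernel(12)
  spi <- sequential_predictions(K_id, d)
  first_ctx1 <- ifelse(d$chosen[1] == "a", d$option_a[1], d$option_b[1])
  i2 <- which(d$context == 1)[2]
  y1 <- d$reward[1]
  # prediction for the sampled stimulus at its next appearance: the
  # centered observation is 0 (single observation = its own mean), so the
  # prediction equals the running context mean
  if (d$option_a[i2] == first_ctx1 || d$option_b[i2] == first_ctx1) {
    expect_equal(spi$center_const[i2], y1)
  }
})

test_that("GP marginal likelihood matches a direct multivariate-normal density", {
  K <- unclass(random_psd_kernel(9, 12))
  set.seed(12)
  s <- sample.int(9, 7, replace = TRUE)
  y <- rnorm(7, 0, 5)
  S <- K[s, s] + 0.01 * diag(7)
  direct <- -0.5 * drop(t(y) %*% solve(S, y)) -
    0.5 * determinant(S)$modulus[1] - 0.5 * 7 * log(2 * pi)
  expect_equal(gp_log_marginal(K, s, y, 0.01), direct, tolerance = 1e-10)
  expect_equal(gp_log_marginal(K, integer(0), numeric(0)), 0)
})

test_that("map posterior probability behaves at the boundaries and converges", {
  lay <- fixture_layout()
  ctxs <- fixture_contexts(lay)
  K_sp <- gaussian_kernel(euclidean_distances(lay), lambda = 4)
  K_id <- identity_kernel(12)
  d <- simulate_choices(K_sp, ctxs, temperature = 5, seed = 2)
  expect_equal(map_posterior_probability(d, K_sp, K_id, t = 0), 0.5)
  # identical kernels: 0.5 at every horizon
  for (t in c(5, 50, 100)) {
    expect_equal(map_posterior_probability(d, K_sp, K_sp, t = t), 0.5)
  }
  # rewards drawn exactly from the spatial kernel's generative model (one
  # latent function per context, observation noise sd 0.1): with reward
  # observations covering the stimulus set and substantial spatial
  # correlation (the Bayes factor is limited by correlation strength, not
  # trial count, once every stimulus value is pinned down), the spatial
  # model's evidence dominates the mean tracker's
  set.seed(31)
  K_sp <- gaussian_kernel(euclidean_distances(lay), lambda = 8)
  K <- unclass(K_sp)
  chl <- chol(K + 1e-8 * diag(12))
  probs <- sapply(1:20, function(r) {
    f1 <- drop(t(chl) %*% rnorm(12))
    f2 <- drop(t(chl) %*% rnorm(12))
    s <- as.vector(replicate(9, sample.int(12)))[1:100]
    dd <- data.frame(trial = 1:100,
                     context = rep(rep(1:2, each = 10), 5),
                     option_a = s, option_b = (s %% 12) + 1L,
                     chosen = "a")
    dd$reward <- ifelse(dd$context == 1, f1[s], f2[s]) + rnorm(100, 0, 0.1)
    map_posterior_probability(dd, K_sp, K_id, t = 100)
  })
  expect_gt(mean(probs > 0.5), 0.75)
  expect_gt(mean(probs), 0.6)
})
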