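test_that("adaptation regressors apply the exclusion rules and z-score per block", {
  D_sp <- euclidean_distances(fixture_layout())
  D_pr <- kernel_distance(gaussian_kernel(D_sp, 4))
  ev <- data.frame(onset = c(0, 3, 6, 9, 12, 0, 3, 6),
                   block = c(1, 1, 1, 1, 1, 2, 2, 2),
                   stimulus = c(1, 1, 2, 3, 9, 5, 6, 6),
                   after_choice = c(FALSE, FALSE, FALSE, TRUE, FALSE,
                                    FALSE, FALSE, FALSE))
  # block 2 has a single included event, whose z-score is degenerate
  w <- capture_warnings(rg <- adaptation_regressors(ev, D_sp, D_pr))
  expect_true(all(grepl("degenerate", w)))
  # first of block, repeats, and post-choice events excluded
  expect_equal(rg$included, c(FALSE, FALSE, TRUE, FALSE, TRUE,
                              FALSE, TRUE, FALSE))
  expect_equal(rg$trial_type[c(2, 8)], c("repeat", "repeat"))
  expect_true(all(is.na(rg$spatial_distance[!rg$included])))
  # z-scored per block over included events
  for (b in 1:2) {
    v <- rg$spatial_distance[rg$block == b & rg$included]
    if (length(v) > 1) {
      expect_equal(mean(v), 0, tolerance = 1e-10)
      expect_equal(sd(v), 1, tolerance = 1e-10)
    }
  }
  # locality: excluding an event does not change other events' values
  ev2 <- ev
  ev2$after_choice[4] <- FALSE
  rg2 <- suppressWarnings(adaptation_regressors(ev2, D_sp, D_pr))
  expect_equal(rg2$included[c(3, 5, 7)], rep(TRUE, 3))
  # degenerate (constant) distances are zeroed with a warning
  D0 <- matrix(1, 12, 12); diag(D0) <- 0
  ev3 <- data.frame(onset = 0:3, block = 1, stimulus = c(1, 2, 3, 4))
  w3 <- capture_warnings(rg3 <- adaptation_regressors(ev3, D0, D0))
  expect_true(any(grepl("degenerate", w3)))
  expect_equal(rg3$spatial_distance[rg3$included], rep(0, 3))
  # deterministic regeneration
  expect_identical(rg, suppressWarnings(adaptation_regressors(ev, D_sp, D_pr)))
})

test_that("kernel-induced distances are valid distances", {
  K <- gaussian_kernel(euclidean_distances(fixture_layout()), 4)
  D <- kernel_distance(K)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 12))
  expect_true(all(D >= 0))
  expect_equal(kernel_distance(K, "one_minus"), 1 - unclass(K),
               ignore_attr = TRUE)
})

test_that("compositional RPEs match a from-scratch batch GP oracle", {
  lay <- fixture_layout()
  ctxs <- fixture_contexts(lay)
  K <- unclass(compose_kernels(gaussian_kernel(euclidean_distances(lay), 4),
                               identity_kernel(12)))
  d <- simulate_choices(K, ctxs, temperature = 5, seed = 13)
  sp <- sequential_predictions(K, d)
  sp$reward <- d$reward
  rpe <- compositional_rpe(sp)
  expect_equal(mean(rpe$rpe_demeaned), 0, tolerance = 1e-12)
  # batch oracle per trial
  for (i in c(1, 5, 42, 100)) {
    prev <- d[seq_len(i - 1), , drop = FALSE]
    prev <- prev[prev$context == d$context[i], , drop = FALSE]
    s_prev <- ifelse(prev$chosen == "a", prev$option_a, prev$option_b)
    mu <- if (nrow(prev)) mean(prev$reward) else 0
    m <- gp_posterior_mean(K, s_prev, prev$reward - mu, 0.01) + mu
    s_ch <- ifelse(d$chosen[i] == "a", d$option_a[i], d$option_b[i])
    expect_equal(rpe$rpe[i], unname(d$reward[i] - m[s_ch]), tolerance = 1e-8)
  }
  # interpolation limit: a revisited stimulus with deterministic reward has
  # near-zero RPE once observed (noise variance is small)
  s_ch <- ifelse(d$chosen == "a", d$option_a, d$option_b)
  revisit <- which(duplicated(paste(d$context, s_ch)))
  expect_lt(median(abs(rpe$rpe[revisit])), 2)
})

test_that("relative map accuracy is zero for identical kernels and signed correctly", {
  rpe <- rnorm(50)
  r0 <- relative_map_accuracy(rpe, rpe)
  expect_equal(r0$value, rep(0, 50))
  r1 <- relative_map_accuracy(rpe_spatial = rep(0.1, 10),
                              rpe_predictive = rep(2, 10))
  expect_true(all(r1$value > 0))  # spatial map predicted better
  expect_equal(mean(r1$value_demeaned), 0, tolerance = 1e-12)
})

test_that("weight-update regressor telescopes and demeans", {
  w <- plogis(seq(-4, 4, length.out = 60))
  u <- weight_update_regressor(w)
  expect_equal(sum(u$update), w[60] - w[1], tolerance = 1e-12)
  expect_equal(mean(u$update_demeaned), 0, tolerance = 1e-12)
  expect_true(all(u$update > 0))
  expect_equal(which.max(u$update), 30, tolerance = 1)
  expect_equal(weight_update_regressor(rep(0.3, 5))$update, rep(0, 4))
  expect_error(weight_update_regressor(0.5), "at least 2")
})

test_that("chosen/unchosen value regressors are demeaned and consistent", {
  lay <- fixture_layout()
  ctxs <- fixture_contexts(lay)
  K <- unclass(gaussian_kernel(euclidean_distances(lay), 4))
  d <- simulate_choices(K, ctxs, temperature = 5, seed = 17)
  sp <- sequential_predictions(K, d)
  cv <- choice_value_regressors(sp)
  expect_equal(mean(cv$chosen_value), 0, tolerance = 1e-12)
  expect_equal(mean(cv$unchosen_value), 0, tolerance = 1e-12)
  i <- which(d$chosen == "a")[5]
  expect_equal(cv$chosen_value_raw[i], sp$pred_a[i])
  expect_equal(cv$unchosen_value_raw[i], sp$pred_b[i])
})
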