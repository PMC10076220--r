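test_that("stimulus placement satisfies arena invariants and is deterministic", {
  cfg <- tiny_arena()
  lay <- place_stimuli(cfg, seed = 1)
  expect_equal(nrow(lay$coords), 12)
  expect_true(all(sqrt(rowSums(lay$coords^2)) < cfg$radius))
  D <- euclidean_distances(lay)
  expect_true(all(D[lower.tri(D)] >= cfg$min_separation))
  expect_identical(lay, place_stimuli(cfg, seed = 1))
  expect_false(identical(lay$coords, place_stimuli(cfg, seed = 2)$coords))
  # degenerate n = 1
  lay1 <- place_stimuli(arena_config(n_stimuli = 1), seed = 7)
  expect_equal(nrow(lay1$coords), 1)
  expect_lt(sqrt(sum(lay1$coords^2)), 15)
  # infeasible separation errors out
  expect_error(place_stimuli(arena_config(radius = 4, n_stimuli = 12,
                                          visibility_radius = 1,
                                          min_separation = 3),
                             seed = 1, max_rejections = 200),
               "min_separation")
})

test_that("exploration trajectories stay in the arena and policies differ", {
  lay <- fixture_layout()
  for (pol in c("stereotyped_order", "border", "lawnmower", "random_walk")) {
    tr <- simulate_exploration(lay, pol, n_blocks = 2, seed = 5)
    expect_true(all(sqrt(tr$x^2 + tr$y^2) <= lay$radius), label = pol)
    expect_true(all(diff(tr$t) > 0), label = pol)
  }
  expect_error(simulate_exploration(lay, "zigzag"), "arg")
  # determinism
  expect_identical(simulate_exploration(lay, "random_walk", seed = 9),
                   simulate_exploration(lay, "random_walk", seed = 9))
})

test_that("stereotyped exploration yields a near-periodic tour over stimuli", {
  lay <- fixture_layout()
  tour <- c(3, 7, 1, 12, 5, 9, 2, 11, 4, 8, 6, 10)
  tr <- simulate_exploration(lay, "stereotyped_order", n_blocks = 3, seed = 2,
                             tour = tour)
  v <- extract_visits(tr, lay, 3)
  # the commanded tour must appear as an ordered subsequence in every block:
  # walking directly between stimuli can clip other discs en route, so test
  # subsequence containment, not equality
  is_subseq <- function(sub, seq) {
    j <- 1
    for (s in seq) if (j <= length(sub) && s == sub[j]) j <- j + 1
    j > length(sub)
  }
  expect_true(is_subseq(rep(tour, 3), v))
})

test_that("policy separation: tour and random-walk transition structure differ", {
  lay <- fixture_layout()
  emp_T <- function(v, n = 12) {
    Tm <- matrix(0, n, n)
    for (i in seq_len(length(v) - 1)) Tm[v[i], v[i + 1]] <- Tm[v[i], v[i + 1]] + 1
    Tm / pmax(rowSums(Tm), 1)
  }
  frob <- function(A, B) sqrt(sum((A - B)^2))
  d_cross <- d_within <- numeric(0)
  for (seed in 1:20) {
    tour <- simulate_exploration(lay, "stereotyped_order", n_blocks = 3,
                                 seed = seed)
    rw1 <- simulate_exploration(lay, "random_walk", n_blocks = 3, seed = seed)
    rw2 <- simulate_exploration(lay, "random_walk", n_blocks = 3,
                                seed = seed + 1000)
    Tt <- emp_T(extract_visits(tour, lay, 3))
    T1 <- emp_T(extract_visits(rw1, lay, 3))
    T2 <- emp_T(extract_visits(rw2, lay, 3))
    d_cross <- c(d_cross, frob(Tt, T1))
    d_within <- c(d_within, frob(T1, T2))
  }
  expect_gt(mean(d_cross), mean(d_within))
})

test_that("visit extraction debounces and handles empty cases", {
  lay <- stimulus_layout(cbind(c(0, 8), c(0, 0)), radius = 15)
  # straight pass within 2 units of stimulus 1 only
  tr <- data.frame(participant_id = 1, block_id = 1, t = 1:21,
                   x = seq(-10, 10, 1), y = rep(2, 21))
  expect_identical(extract_visits(tr, lay, 3), c(1L, 2L))
  # loop through stimulus 1's disc twice with an exit between
  xs <- c(seq(-5, 5, 1), seq(5, -5, -1))
  tr2 <- data.frame(participant_id = 1, block_id = 1, t = seq_along(xs),
                    x = xs, y = 0)
  lay1 <- stimulus_layout(cbind(0, 0), radius = 15)
  expect_identical(extract_visits(tr2, lay1, 3), c(1L, 1L))
  # never within reach
  tr3 <- data.frame(participant_id = 1, block_id = 1, t = 1:3,
                    x = c(10, 11, 12), y = c(10, 10, 10))
  expect_identical(extract_visits(tr3, lay, 3), integer(0))
  expect_identical(extract_visits(tr3[0, ], lay, 3), integer(0))
})

test_that("reward contexts satisfy the generation constraints", {
  lay <- fixture_layout()
  for (seed in c(11, 12, 13)) {
    ctxs <- make_reward_contexts(lay, seed = seed)
    v1 <- ctxs[[1]]$values; v2 <- ctxs[[2]]$values
    expect_true(all(v1 >= 0 & v1 <= 100))
    expect_true(all(v2 >= 0 & v2 <= 100))
    expect_lte(abs(sum(v1) - sum(v2)), 30)
    expect_setequal(c(v1[ctxs[[1]]$inference], v2[ctxs[[2]]$inference]),
                    c(71, 3, 72, 13))
    # re-test the decorrelation constraint independently of the generator
    D <- euclidean_distances(lay)
    dv <- c(abs(outer(v1, v1, "-"))[lower.tri(D)],
            abs(outer(v2, v2, "-"))[lower.tri(D)])
    expect_gt(stats::cor.test(rep(D[lower.tri(D)], 2), dv)$p.value, 0.05)
  }
  expect_false(identical(make_reward_contexts(lay, 1)[[1]]$values,
                         make_reward_contexts(lay, 2)[[1]]$values))
})

test_that("GP agents behave sensibly in the limits and improve over trials", {
  lay <- fixture_layout()
  ctxs <- fixture_contexts(lay)
  D <- euclidean_distances(lay)
  K <- gaussian_kernel(D, lambda = 4)
  expect_error(simulate_choices(K, ctxs, temperature = 0), "temperature")
  # near-greedy limit after substantial experience: mostly correct choices
  d_greedy <- simulate_choices(K, ctxs, temperature = 1e-6, seed = 4)
  cc <- correct_choices(d_greedy, ctxs)
  expect_gt(mean(cc[51:100], na.rm = TRUE), 0.9)
  # random limit
  d_rand <- simulate_choices(K, ctxs, n_trials = 400, temperature = 1e6,
                             seed = 4)
  expect_lt(abs(mean(d_rand$chosen == "a") - 0.5), 0.08)
  # identity-kernel agent, first encounter of never-sampled options: both
  # posterior means equal the prior, so P(a) is exactly 0.5
  d1 <- simulate_choices(identity_kernel(12), ctxs, n_trials = 1, seed = 1)
  expect_true(d1$chosen %in% c("a", "b"))
  # inference stimuli never presented; schedule and rewards are consistent
  d5 <- simulate_choices(K, ctxs, seed = 5)
  inf <- c(ctxs[[1]]$inference, ctxs[[2]]$inference)
  expect_false(any(c(d5$option_a, d5$option_b) %in% inf))
  expect_equal(d5$context, rep(rep(1:2, each = 10), 5))
  vals <- ifelse(d5$chosen == "a", d5$option_a, d5$option_b)
  expect_equal(d5$reward,
               unname(sapply(seq_len(100), function(i)
                 ctxs[[d5$context[i]]]$values[vals[i]])))
  # learning: second-half accuracy beats first half in aggregate (20 seeds)
  acc <- sapply(1:20, function(s) {
    d <- simulate_choices(K, ctxs, temperature = 5, seed = s)
    cc <- correct_choices(d, ctxs)
    c(mean(cc[1:50], na.rm = TRUE), mean(cc[51:100], na.rm = TRUE))
  })
  expect_gt(mean(acc[2, ]), mean(acc[1, ]))
})

test_that("generated cohorts are deterministic in the master seed", {
  a <- generate_cohort(n_participants = 2, agent = "spatial", seed = 42,
                       n_blocks = 2)
  b <- generate_cohort(n_participants = 2, agent = "spatial", seed = 42,
                       n_blocks = 2)
  expect_identical(a$participants[[1]]$dataset, b$participants[[1]]$dataset)
  expect_identical(a$participants[[2]]$trajectory, b$participants[[2]]$trajectory)
  expect_identical(a$contexts[[1]]$values, b$contexts[[1]]$values)
})
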