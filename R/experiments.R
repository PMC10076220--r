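# Self-contained validation experiments: parameter recovery, model
# recovery, weight dynamics, regressor sanity, and bootstrap calibration.
# These drive the acceptance checks and the analysis scripts.

#' Random symmetric row-stochastic transition matrix
#'
#' Generates the transition matrix of a reversible chain with uniform
#' stationary distribution: symmetric positive weights balanced to doubly
#' stochastic by Sinkhorn iteration.
#'
#' @param n Number of states.
#' @param seed Integer seed.
#' @export
random_symmetric_chain <- function(n, seed) {
  with_seed(seed, {
    W <- matrix(stats::runif(n * n), n, n)
    W <- W + t(W)
    for (i in 1:200) {
      W <- W / rowSums(W)
      W <- (W + t(W)) / 2
    }
    W / rowSums(W)
  })
}

#' Successor-representation round-trip error
#'
#' For random reversible transition matrices, builds the analytic successor
#' matrix `M = (I - gamma T)^-1` and recovers T through the inversion
#' pipeline; reports the worst absolute entry error.
#'
#' @param n_rep Number of random chains.
#' @param n_states States per chain.
#' @param gamma Discount.
#' @param seed Integer seed.
#' @return Maximum absolute error over all replicates.
#' @export
sr_roundtrip_error <- function(n_rep = 100, n_states = 12, gamma = 0.9,
                               seed = 1) {
  max(vapply(seq_len(n_rep), function(r) {
    T0 <- random_symmetric_chain(n_states, sub_seed(seed, r))
    M0 <- solve(diag(n_states) - gamma * T0)
    max(abs(successor_to_transition(M0, gamma = gamma)$T - T0))
  }, numeric(1)))
}

#' Model-recovery confusion experiment
#'
#' Generates cohorts of GP agents from each of the four generalization
#' models, runs the full fitting pipeline (grid search, LOO-CV, BMS) on
#' each, and records which model wins the posterior frequency.
#'
#' @param n_seeds Cohorts per generating agent.
#' @param n_participants Synthetic participants per cohort.
#' @param n_trials Choice trials per participant.
#' @param seed Master seed.
#' @param agents Generating models.
#' @return Data frame: `agent`, `seed`, `winner`, plus one frequency column
#'   per fitted model.
#' @export
confusion_experiment <- function(n_seeds = 10, n_participants = 24,
                                 n_trials = 100, seed = 1,
                                 agents = c("spatial", "predictive",
                                            "compositional", "identity")) {
  models <- c("spatial", "predictive", "compositional", "identity")
  rows <- list()
  for (s in seq_len(n_seeds)) {
    for (ag in agents) {
      cell_seed <- sub_seed(seed, 1000 * s + match(ag, models))
      ch <- generate_cohort(n_participants = n_participants, agent = ag,
                            seed = cell_seed, n_trials = n_trials)
      cmp <- compare_models(ch, models = models, seed = cell_seed)
      f <- cmp$comparison$frequency
      rows[[length(rows) + 1]] <- data.frame(
        agent = ag, seed = s, winner = names(which.max(f)),
        t(as.matrix(f)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Weight-dynamics recovery experiment
#'
#' Cohorts of agents that switch from the predictive to the spatial map
#' mid-task; fits trial-wise spatial weights (with grid-searched spatial
#' and predictive hyperparameters) and summarises, per cohort, the mean
#' logistic slope of the weight time-series and the change in mean weight
#' from the first to the last decile of trials.
#'
#' @inheritParams confusion_experiment
#' @param switch_trial Trial at which agents switch maps.
#' @return Data frame per seed: `mean_slope`, `first_decile_w`,
#'   `last_decile_w`.
#' @export
weight_dynamics_experiment <- function(n_seeds = 20, n_participants = 12,
                                       switch_trial = 51L, seed = 1) {
  rows <- lapply(seq_len(n_seeds), function(s) {
    ch <- generate_cohort(n_participants = n_participants, agent = "switch",
                          seed = sub_seed(seed, 7000 + s),
                          switch_trial = switch_trial)
    gs_sp <- grid_search_hyperparams(ch, "spatial")
    gs_pr <- grid_search_hyperparams(ch, "predictive")
    sp <- gs_sp$predictions
    pr <- gs_pr$predictions
    wt <- trialwise_weights(sp$pred_diff, pr$pred_diff, sp$choice,
                            sp$participant, sp$trial)
    slopes <- vapply(split(wt, wt$participant),
                     function(d) fit_weight_slope(d$w, d$trial), numeric(1))
    n_tr <- max(wt$trial)
    dec <- ceiling(n_tr / 10)
    data.frame(seed = s, mean_slope = mean(slopes),
               first_decile_w = mean(wt$w[wt$trial <= dec]),
               last_decile_w = mean(wt$w[wt$trial > n_tr - dec]))
  })
  do.call(rbind, rows)
}

#' Reward contexts drawn from a spatial Gaussian process
#'
#' Samples one latent value function per context from a GP with the
#' Gaussian kernel over the layout's distances, rescales it to the 0-100
#' point range, and designates inference stimuli with the standard true
#' values. Used to emulate rewards that are genuinely organised in space.
#'
#' @param layout A `stimulus_layout`.
#' @param seed Integer seed.
#' @param lambda Lengthscale of the generating kernel.
#' @return List of two `reward_context` objects.
#' @export
contexts_from_gp <- function(layout, seed, lambda = 4) {
  n <- n_stimuli(layout)
  K <- unclass(gaussian_kernel(euclidean_distances(layout), lambda))
  ch <- chol(K + 1e-8 * diag(n))
  with_seed(seed, {
    inf_ids <- sample.int(n, 4)
    vals <- lapply(1:2, function(cc) {
      f <- drop(t(ch) %*% stats::rnorm(n))
      v <- round(100 * (f - min(f)) / max(diff(range(f)), 1e-9))
      pmin(pmax(v, 0), 100)
    })
    v1 <- vals[[1]]; v2 <- vals[[2]]
    inf1 <- c(high = inf_ids[1], low = inf_ids[2])
    inf2 <- c(high = inf_ids[3], low = inf_ids[4])
    v1[inf1] <- c(71, 3); v2[inf2] <- c(72, 13)
    names(v1) <- names(v2) <- rownames(layout$coords)
    list(reward_context(1L, v1, inf1), reward_context(2L, v2, inf2))
  })
}

#' Regressor sanity experiment
#'
#' With rewards organised in space (GP-sampled contexts) and spatial
#' agents, computes per cohort the mean relative-map-accuracy value (which
#' should be positive: outcomes are more consistent with the spatial map)
#' and the mean absolute correlation between relative map accuracy and the
#' compositional reward prediction error.
#'
#' @inheritParams confusion_experiment
#' @return Data frame per seed: `rma_mean`, `abs_cor`.
#' @export
map_accuracy_experiment <- function(n_seeds = 10, n_participants = 8,
                                    seed = 1) {
  rows <- lapply(seq_len(n_seeds), function(s) {
    s_cell <- sub_seed(seed, 8000 + s)
    cfg <- arena_config()
    layout <- place_stimuli(cfg, sub_seed(s_cell, 1))
    ctxs <- contexts_from_gp(layout, sub_seed(s_cell, 2), lambda = 4)
    ch <- generate_cohort(n_participants = n_participants, agent = "spatial",
                          seed = s_cell, contexts = ctxs)
    sp <- cohort_predictions(ch, "spatial", lambda = 4)
    pr <- cohort_predictions(ch, "predictive", eta = 0.1)
    co <- cohort_predictions(ch, "compositional", lambda = 4, eta = 0.1)
    rma_means <- cors <- numeric(0)
    for (id in unique(sp$participant)) {
      r <- sp$participant == id
      rpe_s <- sp$reward[r] - sp$pred_chosen[r]
      rpe_p <- pr$reward[r] - pr$pred_chosen[r]
      rpe_c <- co$reward[r] - co$pred_chosen[r]
      rma <- relative_map_accuracy(rpe_s, rpe_p)
      rma_means <- c(rma_means, mean(rma$value))
      cors <- c(cors, stats::cor(rma$value, rpe_c))
    }
    data.frame(seed = s, rma_mean = mean(rma_means),
               mean_r = mean(cors), abs_cor = mean(abs(cors)))
  })
  do.call(rbind, rows)
}

#' Bootstrap mediation calibration under the null
#'
#' Simulates datasets with X independent of M (so the indirect effect is
#' zero) and reports how often the bootstrap ab test rejects at `alpha`,
#' together with the worst decomposition error `|ab + c' - c|`.
#'
#' @param n_rep Replicates.
#' @param n Participants per replicate.
#' @param n_boot Bootstrap resamples per replicate.
#' @param alpha Test level.
#' @param seed Integer seed.
#' @return List: `rejection_rate`, `n_rep`, `max_decomposition_error`.
#' @export
mediation_calibration <- function(n_rep = 500, n = 48, n_boot = 1000,
                                  alpha = 0.05, seed = 1) {
  rej <- logical(n_rep)
  max_err <- 0
  for (r in seq_len(n_rep)) {
    dat <- with_seed(sub_seed(seed, 9000 + r), {
      list(x = stats::rnorm(n), m = stats::rnorm(n),
           e = stats::rnorm(n))
    })
    y <- 0.4 * dat$m + dat$e
    med <- mediate(dat$x, dat$m, y, n_boot = n_boot,
                   seed = sub_seed(seed, 9500 + r))
    est <- stats::setNames(med$paths$estimate, med$paths$path)
    max_err <- max(max_err, abs(est["ab"] + est["c_prime"] - est["c"]))
    rej[r] <- stats::setNames(med$paths$p, med$paths$path)["ab"] < alpha
  }
  list(rejection_rate = mean(rej), n_rep = n_rep,
       max_decomposition_error = unname(max_err))
}
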