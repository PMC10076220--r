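#' Generate a full synthetic cohort
#'
#' End-to-end seeded generator standing in for the study's raw data: one
#' arena with hidden stimuli, per-participant exploration trajectories
#' (with per-participant random stereotyped tours by default, which
#' decouples predictive adjacency from spatial proximity), path-integrated
#' location estimates, two reward contexts decorrelated from space, and
#' choices from kernel-specific GP agents.
#'
#' @param n_participants Number of synthetic participants.
#' @param agent Generating model: `"spatial"`, `"predictive"`,
#'   `"compositional"`, `"identity"`, or `"switch"` (predictive map before
#'   `switch_trial`, spatial after — emulates mid-task map switching).
#' @param seed Master integer seed; all stages draw sub-seeds from it.
#' @param config An [arena_config()].
#' @param policy Exploration policy (see [simulate_exploration()]).
#' @param random_tour Use a seeded random stimulus tour per participant for
#'   the stereotyped policy (default `TRUE`).
#' @param n_blocks Exploration blocks per participant.
#' @param step Step length in virtual meters.
#' @param noise_sigma Path-integration noise sd.
#' @param agent_lambda Gaussian lengthscale of the generating spatial map.
#' @param agent_eta SR learning rate of the generating predictive map.
#' @param temperature Agent softmax temperature (reward points).
#' @param n_trials,block_length Choice-task schedule.
#' @param switch_trial Trial at which a `"switch"` agent changes maps.
#' @param contexts Optional pre-built pair of reward contexts (e.g. from
#'   [contexts_from_gp()]); by default decorrelated contexts are generated
#'   by [make_reward_contexts()].
#' @return A [cohort()] with extra fields `layout_true`, `contexts`,
#'   `agent`, and per-participant `trajectory`, `layout_hat`, `kernel`.
#' @export
generate_cohort <- function(n_participants = 24, agent = "compositional",
                            seed = 1, config = arena_config(),
                            policy = "stereotyped_order", random_tour = TRUE,
                            n_blocks = 4, step = 0.5, noise_sigma = 0.001,
                            agent_lambda = 4, agent_eta = 0.1,
                            temperature = 5, n_trials = 100, block_length = 10,
                            switch_trial = 51L, contexts = NULL) {
  layout_true <- place_stimuli(config, sub_seed(seed, 1))
  if (is.null(contexts)) {
    contexts <- make_reward_contexts(layout_true, sub_seed(seed, 2))
  }
  n <- config$n_stimuli
  parts <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    tour <- if (random_tour && policy == "stereotyped_order") {
      with_seed(sub_seed(seed, 400 + i), sample.int(n))
    } else NULL
    traj <- simulate_exploration(layout_true, policy, n_blocks = n_blocks,
                                 step = step, seed = sub_seed(seed, 100 + i),
                                 tour = tour, participant_id = i)
    visits <- extract_visits(traj, layout_true, config$visibility_radius)
    layout_hat <- suppressWarnings(
      path_integrate(traj, layout_true, noise_sigma = noise_sigma,
                     radius = config$visibility_radius,
                     seed = sub_seed(seed, 200 + i))
    )
    dist_hat <- euclidean_distances(layout_hat)
    part <- list(id = as.character(i), dataset = NULL, distances = dist_hat,
                 visits = visits, trajectory = traj, layout_hat = layout_hat)
    K_sp <- gaussian_kernel(dist_hat, agent_lambda)
    K_pr <- {
      M <- learn_successor(visits, n, gamma = 0.9, eta = agent_eta)
      diffusion_kernel(successor_to_transition(M, gamma = 0.9), 1)
    }
    kernel <- switch(agent,
                     spatial = K_sp,
                     predictive = K_pr,
                     compositional = compose_kernels(K_sp, K_pr),
                     identity = identity_kernel(n),
                     switch = K_pr,
                     stop("unknown agent kind: ", agent))
    switch_kernel <- if (agent == "switch") K_sp else NULL
    part$dataset <- simulate_choices(kernel, contexts, n_trials = n_trials,
                                     block_length = block_length,
                                     temperature = temperature,
                                     seed = sub_seed(seed, 300 + i),
                                     participant_id = i,
                                     switch_kernel = switch_kernel,
                                     switch_trial = if (agent == "switch")
                                       switch_trial else NULL)
    part$kernel <- kernel
    parts[[i]] <- part
  }
  chrt <- cohort(parts, n_stimuli = n)
  chrt$layout_true <- layout_true
  chrt$contexts <- contexts
  chrt$agent <- agent
  chrt
}
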