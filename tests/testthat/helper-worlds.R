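# Small fixtures built in code, shared across test files.

tiny_arena <- function() arena_config(radius = 15, n_stimuli = 12,
                                      visibility_radius = 3,
                                      min_separation = 3)

# a fixed regression layout: 8 points on a ring plus 4 inner points
fixture_layout <- function() {
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  outer_ring <- cbind(10 * cos(th), 10 * sin(th))
  inner <- cbind(c(4, -4, 0, 0), c(0, 0, 4, -4))
  stimulus_layout(rbind(outer_ring, inner), radius = 15)
}

fixture_contexts <- function(layout = fixture_layout(), seed = 11) {
  make_reward_contexts(layout, seed = seed)
}

# random symmetric row-stochastic transition matrix of a reversible chain
random_reversible_T <- function(n, seed) {
  set.seed(seed)
  W <- matrix(stats::runif(n * n), n, n)
  W <- W + t(W)                       # symmetric positive weights
  # symmetric *and* stochastic requires a doubly stochastic matrix:
  # Sinkhorn-style balancing of the symmetric weights
  for (i in 1:200) {
    W <- W / rowSums(W)
    W <- (W + t(W)) / 2
  }
  W / rowSums(W)
}
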