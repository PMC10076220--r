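#' Simulate a GP agent performing the choice task
#'
#' At every trial the agent computes GP posterior means for both presented
#' options, conditioned on all rewards it has observed so far in the current
#' context (mean-centered per context), and picks option a with probability
#' `plogis((m_a - m_b) / temperature)`. The revealed reward is the chosen
#' stimulus' context value. Trials run in alternating context blocks
#' (default 10 trials per block, 100 trials); inference stimuli are never
#' presented.
#'
#' @param kernel n x n kernel matrix driving the agent's generalisation.
#' @param contexts List of two `reward_context` objects.
#' @param n_trials Total number of trials (default 100).
#' @param block_length Context alternation length (default 10).
#' @param temperature Softmax temperature (> 0), in reward points.
#' @param seed Integer seed.
#' @param sigma2 GP observation noise.
#' @param participant_id Identifier stored in the dataset.
#' @param switch_kernel Optional second kernel: the agent switches to it
#'   from trial `switch_trial` onward (used to emulate mid-task map
#'   switching).
#' @param switch_trial Trial at which `switch_kernel` takes over.
#' @return Choice data frame: `participant_id`, `trial`, `context`,
#'   `option_a`, `option_b`, `chosen`, `reward`.
#' @export
simulate_choices <- function(kernel, contexts, n_trials = 100, block_length = 10,
                             temperature = 5, seed = 1, sigma2 = 0.01,
                             participant_id = 1L, switch_kernel = NULL,
                             switch_trial = NULL) {
  if (temperature <= 0) stop("simulate_choices: temperature must be positive")
  K <- unclass(as.matrix(kernel))
  n <- nrow(K)
  opts <- choice_stimuli(contexts, n)
  if (length(opts) < 2) stop("simulate_choices: fewer than 2 choice stimuli")
  vals <- lapply(contexts, function(cc) cc$values)
  with_seed(seed, {
    obs <- lapply(1:2, function(i) list(s = integer(0), y = numeric(0)))
    res <- data.frame(participant_id = participant_id,
                      trial = seq_len(n_trials),
                      context = (((seq_len(n_trials) - 1) %/% block_length) %% 2) + 1L,
                      option_a = NA_integer_, option_b = NA_integer_,
                      chosen = NA_character_, reward = NA_integer_)
    for (i in seq_len(n_trials)) {
      Ki <- if (!is.null(switch_kernel) && !is.null(switch_trial) &&
                i >= switch_trial) unclass(as.matrix(switch_kernel)) else K
      cc <- res$context[i]
      pair <- sample(opts, 2)
      S <- obs[[cc]]
      mu <- if (length(S$y)) mean(S$y) else 0
      m <- gp_posterior_mean(Ki, S$s, S$y - mu, sigma2)
      p_a <- stats::plogis((m[pair[1]] - m[pair[2]]) / temperature)
      ch_a <- stats::runif(1) < p_a
      s_ch <- if (ch_a) pair[1] else pair[2]
      rew <- vals[[cc]][s_ch]
      obs[[cc]]$s <- c(S$s, s_ch)
      obs[[cc]]$y <- c(S$y, rew)
      res$option_a[i] <- pair[1]
      res$option_b[i] <- pair[2]
      res$chosen[i] <- if (ch_a) "a" else "b"
      res$reward[i] <- rew
    }
    res
  })
}

#' Fraction of reward-maximising choices in a choice dataset
#'
#' @param dataset Choice data frame.
#' @param contexts List of two `reward_context` objects.
#' @return Logical vector, one entry per trial with distinct option values.
#' @export
correct_choices <- function(dataset, contexts) {
  va <- mapply(function(cc, s) contexts[[cc]]$values[s],
               dataset$context, dataset$option_a)
  vb <- mapply(function(cc, s) contexts[[cc]]$values[s],
               dataset$context, dataset$option_b)
  ifelse(va == vb, NA,
         (dataset$chosen == "a") == (va > vb))
}
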