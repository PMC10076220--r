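#' Assemble a cohort for choice modeling
#'
#' A cohort bundles, per participant, everything the generalization models
#' need: the choice dataset, the spatial distance matrix (from the
#' participant's path-integrated stimulus locations), and the stimulus
#' visit sequence (for the successor representation).
#'
#' @param participants List; each element a list with `id`, `dataset`
#'   (choice data frame), `distances` (n x n spatial distance matrix) and
#'   `visits` (integer visit sequence).
#' @param n_stimuli Number of stimuli.
#' @param gamma SR discount (default 0.9).
#' @param lambda_diff Diffusion-kernel lengthscale (default 1).
#' @param sigma2 GP observation noise (default 0.01).
#' @return Object of class `cohort`.
#' @export
cohort <- function(participants, n_stimuli, gamma = 0.9, lambda_diff = 1,
                   sigma2 = 0.01) {
  stopifnot(length(participants) >= 1)
  ids <- vapply(participants, function(p) as.character(p$id), "")
  names(participants) <- ids
  structure(list(participants = participants, n_stimuli = n_stimuli,
                 gamma = gamma, lambda_diff = lambda_diff, sigma2 = sigma2),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort:", length(x$participants), "participants,", x$n_stimuli,
      "stimuli,", sum(vapply(x$participants, function(p) nrow(p$dataset), 0)),
      "choice trials\n")
  invisible(x)
}

#' Build a participant's kernel for a given model family
#'
#' @param part A cohort participant entry.
#' @param kind `"spatial"`, `"predictive"`, `"compositional"` or `"identity"`.
#' @param lambda Gaussian-kernel lengthscale (spatial / compositional).
#' @param eta SR learning rate (predictive / compositional).
#' @param n_stimuli,gamma,lambda_diff See [cohort()].
#' @return Kernel matrix.
#' @export
participant_kernel <- function(part, kind, lambda = NULL, eta = NULL,
                               n_stimuli, gamma = 0.9, lambda_diff = 1) {
  spatial <- function() gaussian_kernel(part$distances, lambda)
  predictive <- function() {
    M <- learn_successor(part$visits, n_stimuli, gamma = gamma, eta = eta)
    diffusion_kernel(successor_to_transition(M, gamma = gamma), lambda_diff)
  }
  switch(kind,
         spatial = spatial(),
         predictive = predictive(),
         compositional = compose_kernels(spatial(), predictive()),
         identity = identity_kernel(n_stimuli),
         stop("unknown model kind: ", kind))
}

#' Sequential model predictions for every participant in a cohort
#'
#' @inheritParams participant_kernel
#' @param chrt A [cohort()].
#' @param kernels Optional named list of precomputed kernels per participant
#'   (overrides `kind`/`lambda`/`eta`).
#' @return Stacked data frame with `participant`, `trial`, `context`,
#'   `choice` (1 = chose option a), `reward`, `pred_diff`, `pred_chosen`,
#'   `pred_unchosen`, `center_const`.
#' @export
cohort_predictions <- function(chrt, kind = NULL, lambda = NULL, eta = NULL,
                               kernels = NULL) {
  out <- lapply(names(chrt$participants), function(id) {
    part <- chrt$participants[[id]]
    K <- if (!is.null(kernels)) kernels[[id]] else {
      participant_kernel(part, kind, lambda, eta, chrt$n_stimuli,
                         chrt$gamma, chrt$lambda_diff)
    }
    sp <- sequential_predictions(K, part$dataset, sigma2 = chrt$sigma2)
    data.frame(participant = id, trial = sp$trial, context = sp$context,
               choice = as.numeric(part$dataset$chosen == "a"),
               reward = part$dataset$reward,
               pred_diff = sp$pred_diff, pred_chosen = sp$pred_chosen,
               pred_unchosen = sp$pred_unchosen, center_const = sp$center_const)
  })
  do.call(rbind, out)
}

# z-score a predictor within participant; constant columns are left at 0
# and the scale recorded as 1
zscore_within <- function(x, participant) {
  for (id in unique(participant)) {
    r <- participant == id
    mu <- mean(x[r])
    sdv <- stats::sd(x[r])
    x[r] <- if (is.na(sdv) || sdv < 1e-12) 0 else (x[r] - mu) / sdv
  }
  x
}
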