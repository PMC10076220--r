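# Model-derived trial-wise parametric regressors for neuroimaging GLMs.
# Only the regressors are constructed here; design-matrix assembly, HRF
# convolution and GLM estimation belong to the neuroimaging stack.

#' Kernel-induced distance matrix
#'
#' Distance implied by a similarity kernel:
#' `sqrt(K[i, i] + K[j, j] - 2 K[i, j])` (the default), or `1 - K` with
#' `method = "one_minus"`.
#'
#' @param K Kernel matrix.
#' @param method `"kernel"` or `"one_minus"`.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
kernel_distance <- function(K, method = c("kernel", "one_minus")) {
  method <- match.arg(method)
  nm <- dimnames(K)
  K <- matrix(unclass(as.matrix(K)), nrow(K))  # strip kernel attributes
  if (method == "one_minus") {
    D <- 1 - K
  } else {
    d <- diag(K)
    D <- sqrt(pmax(outer(d, rep(1, length(d))) + outer(rep(1, length(d)), d) -
                     2 * K, 0))
  }
  diag(D) <- 0
  if (!is.null(nm) && !is.null(nm[[1]])) dimnames(D) <- list(nm[[1]], nm[[1]])
  D
}

# z-score, flagging degenerate columns (constant): zeroed with a warning
zscore_or_zero <- function(x, label = "column") {
  s <- stats::sd(x, na.rm = TRUE)
  if (is.na(s) || s < 1e-12) {
    warning("adaptation_regressors: degenerate ", label, "; zeroed")
    return(list(values = ifelse(is.na(x), NA, 0), degenerate = TRUE))
  }
  list(values = (x - mean(x, na.rm = TRUE)) / s, degenerate = FALSE)
}

#' Adaptation (repetition) distance regressors for a viewing sequence
#'
#' For each stimulus presentation, the spatial and the predictive distance
#' to the immediately preceding stimulus, z-scored per block. Excluded from
#' the parametric columns (values `NA`, `included = FALSE`): the first
#' event of each block (no predecessor), repeats of the immediately
#' preceding stimulus (modeled separately), and events immediately
#' following a choice probe.
#'
#' @param events Data frame with columns `onset`, `block`, `stimulus`, and
#'   optionally `after_choice` (logical).
#' @param D_spatial,D_predictive Stimulus distance matrices (see
#'   [kernel_distance()] and [euclidean_distances()]).
#' @param duration Event duration in seconds (default 2).
#' @return Data frame: the events plus `trial_type` (`"stimulus"` or
#'   `"repeat"`), `spatial_distance`, `predictive_distance` (z-scored per
#'   block over included events), `included`.
#' @export
adaptation_regressors <- function(events, D_spatial, D_predictive,
                                  duration = 2) {
  stopifnot(all(c("onset", "block", "stimulus") %in% names(events)))
  ev <- events[order(events$block, events$onset), , drop = FALSE]
  n <- nrow(ev)
  after_choice <- if ("after_choice" %in% names(ev)) ev$after_choice else
    rep(FALSE, n)
  prev <- c(NA_integer_, ev$stimulus[-n])
  first_of_block <- c(TRUE, ev$block[-1] != ev$block[-n])
  prev[first_of_block] <- NA_integer_
  is_repeat <- !is.na(prev) & prev == ev$stimulus
  included <- !first_of_block & !is_repeat & !after_choice
  sp <- pr <- rep(NA_real_, n)
  ok <- included
  sp[ok] <- D_spatial[cbind(prev[ok], ev$stimulus[ok])]
  pr[ok] <- D_predictive[cbind(prev[ok], ev$stimulus[ok])]
  for (b in unique(ev$block)) {
    r <- ev$block == b & included
    if (any(r)) {
      sp[r] <- zscore_or_zero(sp[r], paste("spatial distances in block", b))$values
      pr[r] <- zscore_or_zero(pr[r], paste("predictive distances in block", b))$values
    }
  }
  ev$duration <- duration
  ev$trial_type <- ifelse(is_repeat, "repeat", "stimulus")
  ev$spatial_distance <- sp
  ev$predictive_distance <- pr
  ev$included <- included
  rownames(ev) <- NULL
  ev
}

#' Trial-wise reward prediction errors from a model's sequential predictions
#'
#' `RPE_t = reward_t - predicted value of the chosen stimulus before
#' feedback` (predictions on the raw reward scale, centering re-added by
#' [sequential_predictions()]). The exported column is demeaned.
#'
#' @param seqpred A [sequential_predictions()] table including `reward`
#'   (join from the dataset if absent).
#' @param reward Observed rewards per trial (defaults to `seqpred$reward`).
#' @return Data frame: `trial`, `rpe` (raw), `rpe_demeaned`.
#' @export
compositional_rpe <- function(seqpred, reward = seqpred$reward) {
  stopifnot(!is.null(reward))
  rpe <- reward - seqpred$pred_chosen
  data.frame(trial = seqpred$trial, rpe = rpe, rpe_demeaned = rpe - mean(rpe))
}

#' Relative map accuracy regressor
#'
#' Difference of unsigned reward prediction errors under the predictive and
#' the spatial map: `|RPE_predictive| - |RPE_spatial|`. Positive values mean
#' the outcome was more consistent with (better predicted by) the spatial
#' map. Demeaned for export.
#'
#' @param rpe_spatial,rpe_predictive Raw per-trial RPEs under each map.
#' @return Data frame: `trial`, `value` (raw), `value_demeaned`, with the
#'   sign convention recorded as an attribute.
#' @export
relative_map_accuracy <- function(rpe_spatial, rpe_predictive,
                                  trial = seq_along(rpe_spatial)) {
  v <- abs(rpe_predictive) - abs(rpe_spatial)
  structure(data.frame(trial = trial, value = v,
                       value_demeaned = v - mean(v)),
            sign_convention = "positive = outcome more consistent with the spatial map")
}

#' Spatial-weight update regressor
#'
#' Trial-by-trial change in the spatial weight, `w_t - w_{t-1}` (first
#' trial excluded), demeaned for export. The raw updates telescope:
#' their sum equals `w_T - w_1`.
#'
#' @param w Per-trial spatial weights.
#' @param trial Trial indices.
#' @return Data frame: `trial`, `update` (raw), `update_demeaned`.
#' @export
weight_update_regressor <- function(w, trial = seq_along(w)) {
  if (length(w) < 2) stop("weight_update_regressor: need at least 2 trials")
  upd <- diff(w)
  data.frame(trial = trial[-1], update = upd,
             update_demeaned = upd - mean(upd))
}

#' Chosen and unchosen value regressors
#'
#' Per-trial predicted values of the chosen and the unchosen stimulus under
#' the winning model; demeaned, not orthogonalized.
#'
#' @param seqpred A [sequential_predictions()] table.
#' @return Data frame: `trial`, `chosen_value`, `unchosen_value` (both
#'   demeaned) plus the raw columns.
#' @export
choice_value_regressors <- function(seqpred) {
  data.frame(trial = seqpred$trial,
             chosen_value_raw = seqpred$pred_chosen,
             unchosen_value_raw = seqpred$pred_unchosen,
             chosen_value = seqpred$pred_chosen - mean(seqpred$pred_chosen),
             unchosen_value = seqpred$pred_unchosen - mean(seqpred$pred_unchosen))
}
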