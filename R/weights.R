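# Spatial vs predictive effect decomposition, trial-wise map weights, and
# logistic slopes of the weight time-series.

# fit one of the two reparameterized competition models and return the
# implied per-participant total coefficients on the spatial and predictive
# predictors. Main predictor first, the other entering as (other - main):
# eta = b0 + a1*main + a2*(other - main)  =>  coef_main = a1 - a2,
# coef_other = a2.
competition_fit <- function(main, other, choice, participant, extra = NULL) {
  X <- cbind(main = main, delta = other - main)
  if (!is.null(extra)) X <- cbind(X, extra)
  hier_logistic(X, choice, participant)
}

#' Decompose choice behavior into spatial and predictive effects
#'
#' Fits two hierarchical logistic models with both maps' predicted reward
#' differences: one with the spatial difference as the main predictor and
#' the predictive-minus-spatial difference as the second, and one with the
#' roles inverted (the predictors are correlated, so neither ordering alone
#' is neutral). From each model the implied per-participant (fixed + random)
#' coefficients on the spatial and on the predictive predictor are derived,
#' their absolute values averaged across the two models, and the spatial
#' weight computed as `spatial / (spatial + predictive)`.
#'
#' @param spatial_pred_diff,predictive_pred_diff Per-trial predicted reward
#'   differences from the two maps (at their own best-fitting
#'   hyperparameters). Z-scored within participant before fitting.
#' @param choice 0/1 indicator of choosing option a.
#' @param participant Participant id per trial.
#' @return Data frame per participant: `spatial_effect`,
#'   `predictive_effect`, `spatial_weight` (in \[0, 1\]; 0.5 with a flag if
#'   both effects vanish), `degenerate`.
#' @export
estimate_effects <- function(spatial_pred_diff, predictive_pred_diff, choice,
                             participant) {
  s <- zscore_within(spatial_pred_diff, participant)
  p <- zscore_within(predictive_pred_diff, participant)
  fa <- competition_fit(s, p, choice, participant)   # spatial main
  fb <- competition_fit(p, s, choice, participant)   # predictive main
  ids <- fa$participants
  sp_a <- fa$coef[, "main"] - fa$coef[, "delta"]
  pr_a <- fa$coef[, "delta"]
  sp_b <- fb$coef[, "delta"]
  pr_b <- fb$coef[, "main"] - fb$coef[, "delta"]
  spatial_effect <- (abs(sp_a) + abs(sp_b)) / 2
  predictive_effect <- (abs(pr_a) + abs(pr_b)) / 2
  tot <- spatial_effect + predictive_effect
  degenerate <- tot < 1e-12
  w <- ifelse(degenerate, 0.5, spatial_effect / pmax(tot, 1e-12))
  data.frame(participant = ids, spatial_effect = unname(spatial_effect),
             predictive_effect = unname(predictive_effect),
             spatial_weight = unname(w), degenerate = unname(degenerate),
             row.names = NULL)
}

#' Trial-wise spatial map weights
#'
#' Augments the two competition models of [estimate_effects()] with
#' predictor-by-trial interactions (trial number z-scored), so each
#' participant's implied spatial and predictive coefficients become linear
#' functions of trial. The trial-wise spatial weight is
#' `w_t = |spatial(t)| / (|spatial(t)| + |predictive(t)|)`, averaged over
#' the two parameterizations.
#'
#' @inheritParams estimate_effects
#' @param trial Trial index per row (within participant).
#' @param interactions Set `FALSE` to force the interaction terms to zero,
#'   in which case `w_t` is constant and equals the static spatial weight.
#' @return Data frame: `participant`, `trial`, `w` in \[0, 1\].
#' @export
trialwise_weights <- function(spatial_pred_diff, predictive_pred_diff, choice,
                              participant, trial, interactions = TRUE) {
  s <- zscore_within(spatial_pred_diff, participant)
  p <- zscore_within(predictive_pred_diff, participant)
  z <- zscore_within(as.numeric(trial), participant)
  one_model <- function(main, other) {
    if (interactions) {
      extra <- cbind(main_x_t = main * z, delta_x_t = (other - main) * z)
      f <- competition_fit(main, other, choice, participant, extra = extra)
    } else {
      f <- competition_fit(main, other, choice, participant)
    }
    ids <- f$participants
    idx <- match(as.character(participant), ids)
    a1 <- f$coef[idx, "main"]; a2 <- f$coef[idx, "delta"]
    if (interactions) {
      a3 <- f$coef[idx, "main_x_t"]; a4 <- f$coef[idx, "delta_x_t"]
    } else {
      a3 <- a4 <- 0
    }
    list(main_coef = (a1 - a2) + (a3 - a4) * z,
         other_coef = a2 + if (interactions) a4 * z else 0)
  }
  ma <- one_model(s, p)  # spatial main
  mb <- one_model(p, s)  # predictive main
  # aggregate as in estimate_effects: average the absolute implied
  # coefficients over the two parameterizations, then take the ratio — so
  # with null interactions w_t reduces exactly to the static weight
  spat <- (abs(ma$main_coef) + abs(mb$other_coef)) / 2
  pred <- (abs(ma$other_coef) + abs(mb$main_coef)) / 2
  tot <- spat + pred
  w <- ifelse(tot < 1e-12, 0.5, spat / pmax(tot, 1e-12))
  data.frame(participant = as.character(participant), trial = as.numeric(trial),
             w = unname(w), row.names = NULL)
}

#' Logistic slope of a spatial-weight time-series
#'
#' Fits `w_t ~ plogis(a + b * trial)` by binomial quasi-likelihood on the
#' continuous proportions and returns the slope `b` (per trial).
#'
#' @param w Per-trial weights in \[0, 1\].
#' @param trial Trial index.
#' @return Slope `b` (0 for a constant series).
#' @export
fit_weight_slope <- function(w, trial) {
  stopifnot(all(w >= 0 & w <= 1))
  if (stats::sd(w) < 1e-12) return(0)
  f <- suppressWarnings(
    stats::glm(w ~ trial, family = stats::quasibinomial())
  )
  unname(stats::coef(f)[2])
}
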