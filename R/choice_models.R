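#' Fit the trial-level choice model
#'
#' Mixed-effects logistic regression of choices on the model-predicted
#' reward difference between the two options:
#' `P(choose a) = plogis(beta0 + (beta1 + b_p) * pred_diff)`, with a
#' participant-specific random slope `b_p ~ N(0, tau^2)` and a fixed
#' intercept absorbing side bias.
#'
#' @param pred_diff Predicted reward difference (option a minus option b)
#'   per trial.
#' @param choice 0/1 indicator of choosing option a.
#' @param participant Participant id per trial.
#' @param engine `"glmer"` (lme4, default), `"two_stage"` (the package's
#'   empirical-Bayes engine, used internally by grid search and LOO-CV), or
#'   `"pooled"` (fixed-effects only).
#' @return Object of class `choice_model_fit`: `intercept`, `slope` (fixed),
#'   `participant_slopes` (fixed + random), `tau2`, `loglik`, `engine`.
#' @export
fit_choice_model <- function(pred_diff, choice, participant,
                             engine = c("glmer", "two_stage", "pooled")) {
  engine <- match.arg(engine)
  stopifnot(length(pred_diff) == length(choice),
            length(choice) == length(participant))
  if (stats::sd(pred_diff) < 1e-12) {
    warning("fit_choice_model: degenerate (constant) predictor; slope is ",
            "unidentifiable and reported as 0")
  }
  n_part <- length(unique(participant))
  if (engine == "glmer" && n_part < 2) engine <- "pooled"
  if (engine == "glmer") {
    df <- data.frame(y = choice, x = pred_diff, p = factor(participant))
    fit <- suppressWarnings(suppressMessages(
      lme4::glmer(y ~ x + (0 + x | p), data = df, family = stats::binomial())
    ))
    fe <- lme4::fixef(fit)
    re <- lme4::ranef(fit)$p
    slopes <- stats::setNames(fe[["x"]] + re[["x"]], rownames(re))
    out <- list(intercept = unname(fe[[1]]), slope = unname(fe[["x"]]),
                participant_slopes = slopes,
                tau2 = unname(lme4::VarCorr(fit)$p[1]),
                loglik = as.numeric(stats::logLik(fit)), engine = engine,
                model = fit)
  } else if (engine == "two_stage") {
    hf <- hier_logistic(matrix(pred_diff, ncol = 1,
                               dimnames = list(NULL, "pred_diff")),
                        choice, participant)
    out <- list(intercept = hf$intercept, slope = unname(hf$fixed[1]),
                participant_slopes = stats::setNames(hf$coef[, 1],
                                                     hf$participants),
                tau2 = unname(hf$tau2[1]), loglik = hf$loglik,
                engine = engine, model = hf)
  } else {
    f <- logit_newton(cbind(1, pred_diff), choice)
    slopes <- stats::setNames(rep(f$coef[2], n_part), unique(participant))
    out <- list(intercept = f$coef[1], slope = f$coef[2],
                participant_slopes = slopes, tau2 = 0, loglik = f$loglik,
                engine = engine, model = f)
  }
  structure(out, class = "choice_model_fit")
}

#' @export
print.choice_model_fit <- function(x, ...) {
  cat("Choice model (", x$engine, "): intercept ", round(x$intercept, 3),
      ", slope ", round(x$slope, 3), ", tau2 ", round(x$tau2, 3),
      ", logLik ", round(x$loglik, 2), "\n", sep = "")
  invisible(x)
}

#' Leave-one-trial-out cross-validated choice log-likelihoods
#'
#' Hyperparameters (and the GP predictions, which depend only on
#' experienced rewards, not on the held-out choice label) stay fixed; for
#' each trial the regression is refit without it and the held-out choice is
#' scored using the participant's estimated random effect.
#'
#' @inheritParams fit_choice_model
#' @param chance If `TRUE`, score the chance model (all coefficients 0):
#'   every trial contributes `log(0.5)`.
#' @return Numeric vector of per-trial held-out log-likelihoods.
#' @export
loo_cv <- function(pred_diff, choice, participant, chance = FALSE) {
  if (chance) return(rep(log(0.5), length(choice)))
  X <- matrix(pred_diff, ncol = 1, dimnames = list(NULL, "pred_diff"))
  fit <- hier_logistic(X, choice, participant)
  hier_loo(fit, X, choice, participant)
}

#' Grid-search kernel hyperparameters against choice likelihood
#'
#' Evaluates every grid point by the total fitted log-likelihood of the
#' choice model on the full dataset (pooled logistic objective) and returns
#' the maximiser; ties break toward smaller lambda, then smaller eta.
#'
#' @param chrt A [cohort()].
#' @param kind Model family (`"spatial"`, `"predictive"`,
#'   `"compositional"`, `"identity"`).
#' @param lambda_grid Gaussian lengthscale grid (spatial / compositional).
#' @param eta_grid SR learning-rate grid (predictive / compositional).
#' @return List: `best` (named list `lambda`, `eta` as applicable),
#'   `surface` (data frame with one log-likelihood per grid point),
#'   `predictions` (prediction table at the best grid point).
#' @export
grid_search_hyperparams <- function(chrt, kind,
                                    lambda_grid = c(0.5, 1, 2, 4, 8, 16),
                                    eta_grid = c(0.01, 0.05, 0.1, 0.2, 0.5, 1.0)) {
  grid <- switch(kind,
    spatial = data.frame(lambda = lambda_grid, eta = NA_real_),
    predictive = data.frame(lambda = NA_real_, eta = eta_grid),
    compositional = {
      g <- expand.grid(lambda = lambda_grid, eta = eta_grid,
                       KEEP.OUT.ATTRS = FALSE)
      g[order(g$lambda, g$eta), ]
    },
    identity = data.frame(lambda = NA_real_, eta = NA_real_),
    stop("unknown model kind: ", kind))
  grid$loglik <- NA_real_
  best <- NULL
  best_ll <- -Inf
  best_pred <- NULL
  # cache predictive kernels per eta (shared by predictive and compositional)
  pred_kernels <- list()
  get_pred_K <- function(eta) {
    key <- as.character(eta)
    if (is.null(pred_kernels[[key]])) {
      pred_kernels[[key]] <<- lapply(chrt$participants, function(part) {
        M <- learn_successor(part$visits, chrt$n_stimuli, gamma = chrt$gamma,
                             eta = eta)
        diffusion_kernel(successor_to_transition(M, gamma = chrt$gamma),
                         chrt$lambda_diff)
      })
    }
    pred_kernels[[key]]
  }
  for (i in seq_len(nrow(grid))) {
    la <- grid$lambda[i]; et <- grid$eta[i]
    kernels <- switch(kind,
      spatial = lapply(chrt$participants,
                       function(part) gaussian_kernel(part$distances, la)),
      predictive = get_pred_K(et),
      compositional = {
        pk <- get_pred_K(et)
        stats::setNames(lapply(names(chrt$participants), function(id) {
          compose_kernels(gaussian_kernel(chrt$participants[[id]]$distances, la),
                          pk[[id]])
        }), names(chrt$participants))
      },
      identity = lapply(chrt$participants,
                        function(part) identity_kernel(chrt$n_stimuli)))
    pr <- cohort_predictions(chrt, kernels = kernels)
    x <- zscore_within(pr$pred_diff, pr$participant)
    ll <- logit_newton(cbind(1, x), pr$choice)$loglik
    grid$loglik[i] <- ll
    if (ll > best_ll + 1e-12) {  # strict improvement: ties keep earlier
      best_ll <- ll
      best <- list(lambda = la, eta = et)
      best_pred <- pr
    }
  }
  list(best = best, surface = grid, predictions = best_pred)
}

#' Compare generalization models on a cohort
#'
#' For each model family: grid-search hyperparameters on the full dataset,
#' run leave-one-trial-out CV at the best hyperparameters, sum each
#' participant's held-out log-likelihoods into subject-level evidence, and
#' feed the evidence matrix into random-effects Bayesian model selection.
#'
#' @param chrt A [cohort()].
#' @param models Character vector of model families to compare.
#' @param lambda_grid,eta_grid Hyperparameter grids.
#' @param seed Seed for the exceedance-probability Monte-Carlo.
#' @return List: `comparison` (a [bms()] result), `evidence`
#'   (participants x models), `best` (hyperparameters per model),
#'   `predictions` (per-model prediction tables), `loo` (per-model
#'   per-trial held-out log-likelihoods).
#' @export
compare_models <- function(chrt,
                           models = c("spatial", "predictive",
                                      "compositional", "identity"),
                           lambda_grid = c(0.5, 1, 2, 4, 8, 16),
                           eta_grid = c(0.01, 0.05, 0.1, 0.2, 0.5, 1.0),
                           seed = 1) {
  ids <- names(chrt$participants)
  evidence <- matrix(NA_real_, length(ids), length(models),
                     dimnames = list(ids, models))
  best <- list(); preds <- list(); loos <- list()
  for (m in models) {
    gs <- grid_search_hyperparams(chrt, m, lambda_grid, eta_grid)
    pr <- gs$predictions
    x <- zscore_within(pr$pred_diff, pr$participant)
    ll <- loo_cv(x, pr$choice, pr$participant)
    evidence[, m] <- vapply(ids, function(id) sum(ll[pr$participant == id]), 0)
    best[[m]] <- gs$best
    preds[[m]] <- pr
    loos[[m]] <- ll
  }
  list(comparison = bms(evidence, seed = seed), evidence = evidence,
       best = best, predictions = preds, loo = loos)
}
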