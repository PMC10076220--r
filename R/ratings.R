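# Value-judgment modeling: hierarchical linear regression of ratings on
# model-predicted values, with per-rating LOO-CV and BMS over models.

#' Two-stage empirical-Bayes hierarchical linear regression
#'
#' `y = beta0 + (beta1 + b_p) x + e`, `b_p ~ N(0, tau2)`, `e ~ N(0, sigma2)`.
#' Closed-form per-participant slope posteriors alternate with moment
#' updates of the population parameters.
#'
#' @param x Predictor; `y` response; `participant` ids per row.
#' @return List: `intercept`, `slope`, `tau2`, `sigma2`, `coef`
#'   (per-participant total slopes), `coef_var`, `participants`, `loglik`.
#' @export
hier_linear <- function(x, y, participant, n_iter = 20L) {
  pid <- as.character(participant)
  ids <- unique(pid)
  rows <- split(seq_along(y), factor(pid, levels = ids))
  fit0 <- stats::lm.fit(cbind(1, x), y)
  beta0 <- fit0$coefficients[1]
  beta1 <- if (is.na(fit0$coefficients[2])) 0 else fit0$coefficients[2]
  sigma2 <- max(mean(fit0$residuals^2), 1e-8)
  tau2 <- max(beta1^2 / 4, 1e-4)
  theta <- stats::setNames(rep(beta1, length(ids)), ids)
  V <- stats::setNames(rep(tau2, length(ids)), ids)
  for (it in seq_len(n_iter)) {
    for (k in seq_along(ids)) {
      r <- rows[[k]]
      prec <- sum(x[r]^2) / sigma2 + 1 / tau2
      theta[k] <- (sum(x[r] * (y[r] - beta0)) / sigma2 + beta1 / tau2) / prec
      V[k] <- 1 / prec
    }
    beta1 <- mean(theta)
    tau2 <- min(max(mean((theta - beta1)^2 + V), 1e-6), 1e4)
    fitted_part <- x * theta[match(pid, ids)]
    beta0 <- mean(y - fitted_part)
    sigma2 <- max(mean((y - beta0 - fitted_part)^2), 1e-8)
  }
  res <- y - beta0 - x * theta[match(pid, ids)]
  ll <- sum(stats::dnorm(res, 0, sqrt(sigma2), log = TRUE))
  list(intercept = unname(beta0), slope = unname(beta1), tau2 = unname(tau2),
       sigma2 = unname(sigma2), coef = theta, coef_var = V,
       participants = ids, loglik = ll)
}

# per-rating LOO log-density under the hierarchical linear model; the
# held-out participant slope is re-derived without the held-out rating
hier_linear_loo <- function(fit, x, y, participant) {
  pid <- as.character(participant)
  out <- numeric(length(y))
  for (k in seq_along(fit$participants)) {
    id <- fit$participants[k]
    r <- which(pid == id)
    for (j in r) {
      rr <- setdiff(r, j)
      prec <- sum(x[rr]^2) / fit$sigma2 + 1 / fit$tau2
      th <- (sum(x[rr] * (y[rr] - fit$intercept)) / fit$sigma2 +
               fit$slope / fit$tau2) / prec
      pred <- fit$intercept + x[j] * th
      pv <- fit$sigma2 + x[j]^2 / prec
      out[j] <- stats::dnorm(y[j], pred, sqrt(pv), log = TRUE)
    }
  }
  out
}

#' Model comparison on value ratings
#'
#' Regresses each participant's value ratings on each model's predicted
#' values (hierarchical linear model with a participant-specific random
#' slope), scores every rating by leave-one-out CV, and runs random-effects
#' BMS on the per-participant summed held-out log-densities. A baseline
#' model predicting every rating by a single constant per participant (the
#' mean of the mean tracker's predictions for the non-inference stimuli) is
#' included when `baseline` is supplied.
#'
#' @param ratings Data frame with columns `participant`, `stimulus`,
#'   `rating`.
#' @param predictions Named list; per model either a data frame
#'   (`participant`, `stimulus`, `pred`) or a participants x stimuli matrix.
#' @param baseline Optional named numeric vector: one constant prediction
#'   per participant.
#' @param seed Seed for the BMS Monte-Carlo.
#' @return List: `comparison` (a [bms()] result), `evidence`, `fits`.
#' @export
fit_value_ratings <- function(ratings, predictions, baseline = NULL, seed = 1) {
  stopifnot(all(c("participant", "stimulus", "rating") %in% names(ratings)))
  ids <- unique(as.character(ratings$participant))
  get_pred <- function(pr) {
    if (is.matrix(pr)) {
      pr[cbind(match(as.character(ratings$participant), rownames(pr)),
               ratings$stimulus)]
    } else {
      key_r <- paste(ratings$participant, ratings$stimulus)
      key_p <- paste(pr$participant, pr$stimulus)
      pr$pred[match(key_r, key_p)]
    }
  }
  models <- names(predictions)
  if (!is.null(baseline)) models <- c(models, "baseline")
  evidence <- matrix(NA_real_, length(ids), length(models),
                     dimnames = list(ids, models))
  fits <- list()
  y <- ratings$rating
  for (m in models) {
    x <- if (m == "baseline") {
      unname(baseline[as.character(ratings$participant)])
    } else {
      get_pred(predictions[[m]])
    }
    if (anyNA(x)) stop("fit_value_ratings: missing predictions for model ", m)
    xs <- as.numeric(scale(x))
    if (stats::sd(x) < 1e-12) xs <- rep(0, length(x))
    f <- hier_linear(xs, y, ratings$participant)
    ll <- hier_linear_loo(f, xs, y, ratings$participant)
    evidence[, m] <- vapply(ids, function(id) {
      sum(ll[as.character(ratings$participant) == id])
    }, 0)
    fits[[m]] <- f
  }
  list(comparison = bms(evidence, seed = seed), evidence = evidence,
       fits = fits)
}
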