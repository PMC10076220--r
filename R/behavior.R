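# Behavioral summary measures.

#' Object-location replacement error
#'
#' Euclidean distance between each drop location and the true stimulus
#' location, with the criterion check that the mean error is below 3
#' virtual meters (10% of the arena's diameter).
#'
#' @param drop_positions n x 2 matrix of drop locations (rows matched to
#'   the true layout's stimuli).
#' @param true_layout A `stimulus_layout` (or n x 2 matrix).
#' @return List: `per_stimulus` errors, `mean`, `criterion_met`
#'   (mean < 3 vm).
#' @export
replacement_error <- function(drop_positions, true_layout) {
  C <- if (inherits(true_layout, "stimulus_layout")) true_layout$coords else
    as.matrix(true_layout)
  D <- as.matrix(drop_positions)
  if (nrow(D) != nrow(C) || anyNA(D)) {
    stop("replacement_error: drop positions must match the layout's stimuli")
  }
  err <- sqrt(rowSums((D - C)^2))
  list(per_stimulus = err, mean = mean(err), criterion_met = mean(err) < 3)
}

#' Map reproduction error
#'
#' Root-mean-square error between the z-scored true pairwise stimulus
#' distances and the z-scored pairwise distances of a reproduced
#' arrangement; z-scoring makes the measure scale-invariant.
#'
#' @param reproduced_layout,true_layout `stimulus_layout`s or n x 2
#'   matrices.
#' @return Scalar RMSE.
#' @export
map_reproduction_error <- function(reproduced_layout, true_layout) {
  dv <- function(l) {
    D <- euclidean_distances(l)
    d <- D[lower.tri(D)]
    if (stats::sd(d) < 1e-12) stop("map_reproduction_error: degenerate layout")
    as.numeric(scale(d))
  }
  sqrt(mean((dv(reproduced_layout) - dv(true_layout))^2))
}

#' Inference error
#'
#' Root-mean-square error between a participant's value ratings for the
#' four inference stimuli and their true values (defaults 71, 3, 72, 13).
#'
#' @param ratings Ratings for the inference stimuli, in \[0, 100\], matched
#'   to `true_values`.
#' @param true_values True inference-stimulus values.
#' @return Scalar RMSE.
#' @export
inference_error <- function(ratings, true_values = c(71, 3, 72, 13)) {
  if (length(ratings) != length(true_values) || anyNA(ratings)) {
    stop("inference_error: need one rating per inference stimulus")
  }
  sqrt(mean((ratings - true_values)^2))
}
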