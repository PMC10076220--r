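#' Estimate stimulus locations by path integration
#'
#' Re-integrates the agent's displacements from one time sample to the next,
#' adding Gaussian noise (sd `noise_sigma`) to the location estimate at each
#' time point, and estimates each stimulus' location as the mean of the
#' (noisy) integrated positions recorded while the agent was within `radius`
#' of that stimulus.
#'
#' @param trajectory Trajectory data frame (`t`, `x`, `y`).
#' @param layout_true True `stimulus_layout` (defines proximity).
#' @param noise_sigma Per-step integration noise, in virtual meters.
#' @param radius Proximity radius used to attribute samples to stimuli.
#' @param seed Integer seed for the noise stream.
#' @param fallback_true If `TRUE`, stimuli never approached fall back to
#'   their true coordinates (with a warning); otherwise their rows are `NA`.
#' @return A `stimulus_layout` with `provenance = "path_integrated"` and a
#'   `missing` field naming stimuli that were never approached.
#' @export
path_integrate <- function(trajectory, layout_true, noise_sigma = 0.001,
                           radius = 3, seed = 1, fallback_true = TRUE) {
  stopifnot(nrow(trajectory) > 0)
  P <- as.matrix(trajectory[, c("x", "y")])
  nT <- nrow(P)
  est <- with_seed(seed, {
    eps <- matrix(stats::rnorm(2 * nT, 0, noise_sigma), nT, 2)
    eps[1, ] <- 0  # the starting location is known
    # integrated estimate: true displacements plus accumulated noise
    P + apply(eps, 2, cumsum)
  })
  C <- layout_true$coords
  n <- nrow(C)
  coords <- matrix(NA_real_, n, 2, dimnames = dimnames(C))
  missing <- integer(0)
  for (s in seq_len(n)) {
    near <- sqrt((P[, 1] - C[s, 1])^2 + (P[, 2] - C[s, 2])^2) <= radius
    if (!any(near)) {
      missing <- c(missing, s)
    } else {
      coords[s, ] <- colMeans(est[near, , drop = FALSE])
    }
  }
  if (length(missing) > 0) {
    if (fallback_true) {
      warning("path_integrate: stimuli never approached, using true locations: ",
              paste(missing, collapse = ", "))
      coords[missing, ] <- C[missing, , drop = FALSE]
    }
  }
  # drift can push an estimate marginally outside the disc; widen radius to fit
  rad <- max(layout_true$radius, max(sqrt(rowSums(coords^2)), na.rm = TRUE) + 1e-9)
  stimulus_layout(coords, radius = rad, provenance = "path_integrated",
                  missing = missing)
}

#' Pairwise Euclidean distances between stimuli
#'
#' @param layout A `stimulus_layout` (or bare n x 2 coordinate matrix).
#' @return Symmetric n x n distance matrix (zero diagonal).
#' @export
euclidean_distances <- function(layout) {
  coords <- if (inherits(layout, "stimulus_layout")) layout$coords else as.matrix(layout)
  D <- as.matrix(stats::dist(coords))
  dimnames(D) <- list(rownames(coords), rownames(coords))
  D
}

#' Gaussian (radial basis function) kernel over spatial distances
#'
#' Similarity decays with squared distance:
#' `K[i, j] = sigma_f2 * exp(-d[i, j]^2 / (2 * lambda^2))`.
#'
#' @param distances Symmetric non-negative distance matrix.
#' @param lambda Lengthscale (> 0), in the distance units.
#' @param sigma_f2 Signal variance (kernel diagonal).
#' @return Symmetric positive semi-definite kernel matrix.
#' @export
gaussian_kernel <- function(distances, lambda, sigma_f2 = 1) {
  if (lambda <= 0) stop("gaussian_kernel: lambda must be positive")
  K <- sigma_f2 * exp(-distances^2 / (2 * lambda^2))
  structure(K, kind = "spatial", lambda = lambda, sigma_f2 = sigma_f2)
}
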