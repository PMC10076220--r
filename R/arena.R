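#' Arena configuration
#'
#' Describes the circular virtual arena in which stimuli ("monsters") are
#' hidden. Defaults mirror the study environment: a 15-virtual-meter radius
#' arena holding 12 stimuli, each revealed when the agent comes within a
#' 3-vm visibility radius, with stimuli at least 3 vm apart.
#'
#' @param radius Arena radius in virtual meters.
#' @param n_stimuli Number of stimuli.
#' @param visibility_radius Radius within which a stimulus is revealed.
#' @param min_separation Minimum pairwise distance between stimuli.
#' @return An object of class `arena_config`.
#' @export
arena_config <- function(radius = 15, n_stimuli = 12, visibility_radius = 3,
                         min_separation = 3) {
  stopifnot(radius > visibility_radius, visibility_radius > 0,
            n_stimuli >= 1, min_separation >= 0)
  structure(list(radius = radius, n_stimuli = n_stimuli,
                 visibility_radius = visibility_radius,
                 min_separation = min_separation),
            class = "arena_config")
}

#' Place stimuli in the arena by rejection sampling
#'
#' Draws stimulus coordinates uniformly in the arena disc, rejecting
#' candidates closer than `min_separation` to an already placed stimulus.
#' Deterministic given the seed.
#'
#' @param config An [arena_config()].
#' @param seed Integer seed.
#' @param max_rejections Abort after this many consecutive rejections.
#' @return A `stimulus_layout`: list with `coords` (n x 2 matrix), `radius`,
#'   and `provenance = "true"`.
#' @export
place_stimuli <- function(config, seed, max_rejections = 10000L) {
  stopifnot(inherits(config, "arena_config"))
  with_seed(seed, {
    coords <- matrix(NA_real_, config$n_stimuli, 2,
                     dimnames = list(paste0("s", seq_len(config$n_stimuli)),
                                     c("x", "y")))
    placed <- 0L
    rejections <- 0L
    # keep stimuli a visibility radius away from the wall so their discs
    # are reachable from all sides
    r_max <- config$radius - min(config$visibility_radius, config$radius / 4)
    while (placed < config$n_stimuli) {
      r <- r_max * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      cand <- c(r * cos(th), r * sin(th))
      ok <- placed == 0L ||
        all(sqrt(colSums((t(coords[seq_len(placed), , drop = FALSE]) - cand)^2)) >=
              config$min_separation)
      if (ok) {
        placed <- placed + 1L
        coords[placed, ] <- cand
        rejections <- 0L
      } else {
        rejections <- rejections + 1L
        if (rejections > max_rejections) {
          stop("place_stimuli: could not satisfy min_separation = ",
               config$min_separation, " for ", config$n_stimuli,
               " stimuli after ", max_rejections,
               " rejections; reduce min_separation or n_stimuli")
        }
      }
    }
    stimulus_layout(coords, radius = config$radius, provenance = "true")
  })
}

#' Construct a stimulus layout
#'
#' @param coords n x 2 numeric matrix of stimulus coordinates.
#' @param radius Arena radius the coordinates live in.
#' @param provenance `"true"` or `"path_integrated"`.
#' @param missing Integer ids of stimuli without a location estimate.
#' @return A `stimulus_layout` object.
#' @export
stimulus_layout <- function(coords, radius = 15, provenance = "true",
                            missing = integer(0)) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2)
  if (any(sqrt(rowSums(coords^2)) >= radius + 1e-9, na.rm = TRUE)) {
    stop("stimulus_layout: coordinates outside the arena disc")
  }
  colnames(coords) <- c("x", "y")
  if (is.null(rownames(coords))) rownames(coords) <- paste0("s", seq_len(nrow(coords)))
  structure(list(coords = coords, radius = radius, provenance = provenance,
                 missing = missing),
            class = "stimulus_layout")
}

#' @export
print.stimulus_layout <- function(x, ...) {
  cat("Stimulus layout:", nrow(x$coords), "stimuli in a radius-", x$radius,
      "arena (", x$provenance, ")\n")
  invisible(x)
}

n_stimuli <- function(layout) nrow(layout$coords)
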