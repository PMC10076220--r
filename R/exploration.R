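#' Simulate an exploration trajectory
#'
#' Generates a discrete-step walk through the arena under one of four
#' qualitatively distinct exploration policies observed in free navigation:
#' visiting stimuli in a stereotyped order, circling the arena border,
#' scanning the arena in a lawnmower pattern from top to bottom, or a
#' random walk with a reflective boundary.
#'
#' @param layout A `stimulus_layout` (true coordinates).
#' @param policy One of `"stereotyped_order"`, `"border"`, `"lawnmower"`,
#'   `"random_walk"`.
#' @param n_blocks Number of exploration blocks (one tour / loop / sweep /
#'   walk segment per block).
#' @param step Step length per time sample, in virtual meters.
#' @param seed Integer seed.
#' @param tour For `stereotyped_order`, the commanded stimulus visiting
#'   order (default `1:n`). A seeded random permutation decouples visit
#'   order from spatial proximity.
#' @param participant_id Identifier stored in the trajectory.
#' @param block_id_start Block id of the first block (blocks number
#'   consecutively from it).
#' @return A `data.frame` with columns `participant_id`, `block_id`, `t`,
#'   `x`, `y`; `t` strictly increasing, all positions inside the arena disc.
#' @export
simulate_exploration <- function(layout, policy = c("stereotyped_order", "border",
                                                    "lawnmower", "random_walk"),
                                 n_blocks = 3, step = 0.5, seed = 1,
                                 tour = NULL, participant_id = 1L,
                                 block_id_start = 1L) {
  policy <- match.arg(policy)
  stopifnot(inherits(layout, "stimulus_layout"), n_blocks >= 1, step > 0)
  R <- layout$radius
  with_seed(seed, {
    blocks <- vector("list", n_blocks)
    pos <- c(0, 0)
    heading <- stats::runif(1, 0, 2 * pi)
    for (b in seq_len(n_blocks)) {
      path <- switch(policy,
        stereotyped_order = walk_tour(layout, pos, step,
                                      tour %||% seq_len(n_stimuli(layout))),
        border = walk_border(R, pos, step),
        lawnmower = walk_lawnmower(R, step),
        random_walk = walk_random(R, pos, step, heading,
                                  n_steps = 60L * n_stimuli(layout))
      )
      pos <- path[nrow(path), ]
      blocks[[b]] <- data.frame(participant_id = participant_id,
                                block_id = block_id_start + b - 1L,
                                t = NA_real_, x = path[, 1], y = path[, 2])
    }
    traj <- do.call(rbind, blocks)
    traj$t <- seq_len(nrow(traj))
    rownames(traj) <- NULL
    # clamp numerically marginal positions onto the disc
    r <- sqrt(traj$x^2 + traj$y^2)
    bad <- r > R
    if (any(bad)) {
      sc <- (R * 0.999) / r[bad]
      traj$x[bad] <- traj$x[bad] * sc
      traj$y[bad] <- traj$y[bad] * sc
    }
    traj
  })
}

# straight-line segments from the current position through each stimulus in
# order, dwelling a few samples at each stimulus (as participants do when a
# monster reveals itself; also keeps the position-averaging location
# estimator centered on the stimulus rather than on pass-through chords)
walk_tour <- function(layout, start, step, tour, dwell = 12L) {
  pts <- rbind(start, layout$coords[tour, , drop = FALSE])
  out <- list()
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    d <- sqrt(sum((b - a)^2))
    n <- max(2L, ceiling(d / step))
    fr <- seq(0, 1, length.out = n)
    seg <- cbind(a[1] + fr * (b[1] - a[1]), a[2] + fr * (b[2] - a[2]))
    seg <- rbind(seg, matrix(rep(b, dwell), dwell, 2, byrow = TRUE))
    out[[i]] <- if (i == 1) seg else seg[-1, , drop = FALSE]
  }
  do.call(rbind, out)
}

# one full loop along a ring just inside the wall
walk_border <- function(R, start, step) {
  r0 <- R - 1.5
  th0 <- atan2(start[2], start[1])
  n <- max(8L, ceiling(2 * pi * r0 / step))
  th <- th0 + seq(0, 2 * pi, length.out = n)
  cbind(r0 * cos(th), r0 * sin(th))
}

# horizontal sweeps from top to bottom, alternating direction
walk_lawnmower <- function(R, step, row_gap = 2) {
  ys <- seq(R - row_gap / 2, -(R - row_gap / 2), by = -row_gap)
  out <- list()
  for (i in seq_along(ys)) {
    y <- ys[i]
    xmax <- sqrt(max(R^2 - y^2, 0)) * 0.98
    n <- max(2L, ceiling(2 * xmax / step))
    xs <- seq(-xmax, xmax, length.out = n)
    if (i %% 2 == 0) xs <- rev(xs)
    out[[i]] <- cbind(xs, rep(y, n))
  }
  do.call(rbind, out)
}

# correlated random walk; headings turn toward the center near the wall
walk_random <- function(R, start, step, heading, n_steps, turn_sd = 0.4) {
  pos <- matrix(NA_real_, n_steps, 2)
  p <- start
  h <- heading
  for (i in seq_len(n_steps)) {
    h <- h + stats::rnorm(1, 0, turn_sd)
    cand <- p + step * c(cos(h), sin(h))
    if (sqrt(sum(cand^2)) > R - step) {
      # reflect: head back toward the center with jitter
      h <- atan2(-p[2], -p[1]) + stats::rnorm(1, 0, turn_sd)
      cand <- p + step * c(cos(h), sin(h))
    }
    p <- cand
    pos[i, ] <- p
  }
  pos
}

#' Extract the stimulus visit sequence from a trajectory
#'
#' A visit to a stimulus is recorded at the time sample where the position
#' enters that stimulus' visibility disc from outside it; continuous
#' presence inside the disc counts as a single visit. Visits are ordered by
#' entry time.
#'
#' @param trajectory Trajectory data frame (columns `t`, `x`, `y`).
#' @param layout A `stimulus_layout` in the same arena frame.
#' @param visibility_radius Visit radius in virtual meters.
#' @return Integer vector of visited stimulus ids (possibly empty).
#' @export
extract_visits <- function(trajectory, layout, visibility_radius = 3) {
  if (nrow(trajectory) == 0) return(integer(0))
  P <- as.matrix(trajectory[, c("x", "y")])
  C <- layout$coords
  n <- nrow(C)
  # squared distances samples x stimuli
  d2 <- outer(rowSums(P^2), rep(1, n)) + outer(rep(1, nrow(P)), rowSums(C^2)) -
    2 * P %*% t(C)
  inside <- d2 <= visibility_radius^2
  entered <- inside & !rbind(FALSE, inside[-nrow(inside), , drop = FALSE])
  idx <- which(entered, arr.ind = TRUE)
  if (nrow(idx) == 0) return(integer(0))
  as.integer(idx[order(idx[, 1]), 2])
}
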