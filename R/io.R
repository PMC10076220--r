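# Canonical CSV/JSON readers and writers. All writers round-trip losslessly
# with the readers (bit-exact for integers, <= 1e-12 for reals: full
# precision is written).

#' Write / read a square matrix as CSV with stimulus-id headers
#' @param m Square matrix; `path` file path.
#' @export
write_matrix_csv <- function(m, path) {
  m <- as.matrix(m)
  ids <- rownames(m) %||% paste0("s", seq_len(nrow(m)))
  df <- data.frame(id = ids, m, check.names = FALSE)
  colnames(df) <- c("id", ids)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a trajectory CSV
#'
#' Columns: `participant_id`, `block_id`, `t`, `x`, `y`.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(trajectory[, c("participant_id", "block_id", "t", "x", "y")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) utils::read.csv(path)

#' Write / read a choice dataset CSV
#'
#' Columns: `participant_id`, `trial`, `context`, `option_a`, `option_b`,
#' `chosen`, `reward`.
#' @export
write_choices_csv <- function(dataset, path) {
  utils::write.csv(dataset[, c("participant_id", "trial", "context",
                               "option_a", "option_b", "chosen", "reward")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_choices_csv
#' @export
read_choices_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(chosen = "character"))
  df
}

#' Write / read reward contexts as JSON
#'
#' Stimulus-to-value maps plus inference-stimulus ids per context.
#' @export
write_contexts_json <- function(contexts, path) {
  obj <- lapply(contexts, function(cc) {
    list(context_id = cc$context_id, values = as.list(cc$values),
         inference = as.list(cc$inference))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contexts_json
#' @export
read_contexts_json <- function(path) {
  obj <- jsonlite::read_json(path)
  lapply(obj, function(cc) {
    reward_context(cc$context_id,
                   stats::setNames(unlist(cc$values), names(cc$values)),
                   stats::setNames(unlist(cc$inference), names(cc$inference)))
  })
}

#' Ingest externally deposited behavioral data into a cohort
#'
#' Adapter from the canonical CSV schemas (one choices file and one
#' trajectory file, both holding all participants) to a [cohort()]. Column
#' names are normalised at this boundary; downstream code sees only the
#' canonical types.
#'
#' @param choices_path Choices CSV (canonical schema, see
#'   [write_choices_csv()]).
#' @param trajectories_path Trajectories CSV ([write_trajectory_csv()]).
#' @param layout_true True stimulus layout (for visit extraction and
#'   path-integration attribution).
#' @param visibility_radius Visit radius.
#' @return A [cohort()].
#' @export
ingest_cohort <- function(choices_path, trajectories_path, layout_true,
                          visibility_radius = 3) {
  ch <- read_choices_csv(choices_path)
  tr <- read_trajectory_csv(trajectories_path)
  ids <- unique(ch$participant_id)
  parts <- lapply(ids, function(id) {
    traj <- tr[tr$participant_id == id, , drop = FALSE]
    if (nrow(traj) == 0) stop("ingest_cohort: no trajectory for participant ", id)
    visits <- extract_visits(traj, layout_true, visibility_radius)
    layout_hat <- suppressWarnings(
      path_integrate(traj, layout_true, radius = visibility_radius,
                     seed = sub_seed(1, match(id, ids)))
    )
    list(id = as.character(id),
         dataset = ch[ch$participant_id == id, , drop = FALSE],
         distances = euclidean_distances(layout_hat),
         visits = visits, trajectory = traj, layout_hat = layout_hat)
  })
  chrt <- cohort(parts, n_stimuli = n_stimuli(layout_true))
  chrt$layout_true <- layout_true
  chrt
}
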