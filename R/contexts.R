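#' Generate a pair of reward contexts decorrelated from space
#'
#' Assigns integer stimulus values in \[0, 100\] for two reward contexts such
#' that (i) pooled pairwise absolute value differences are not significantly
#' correlated with pairwise spatial distances (Pearson test at `alpha`),
#' (ii) the total value is similar across contexts, and (iii) each context
#' designates two inference stimuli — never shown in the choice task — with
#' one high and one low true value (defaults 71/3 in context 1 and 72/13 in
#' context 2).
#'
#' @param layout A `stimulus_layout` giving the spatial arrangement.
#' @param seed Integer seed.
#' @param alpha Significance level for the distance-value decorrelation test.
#' @param sum_tol Maximum allowed difference in total value across contexts.
#' @param inference_values List of `c(high, low)` per context.
#' @param max_tries Rejection budget.
#' @return List of two `reward_context` objects (fields `context_id`,
#'   `values` (named integer vector), `inference` (named ids `high`, `low`)).
#' @export
make_reward_contexts <- function(layout, seed, alpha = 0.05, sum_tol = 30,
                                 inference_values = list(c(high = 71, low = 3),
                                                         c(high = 72, low = 13)),
                                 max_tries = 5000L) {
  n <- n_stimuli(layout)
  stopifnot(n >= 6)
  D <- euclidean_distances(layout)
  dvec <- D[lower.tri(D)]
  with_seed(seed, {
    # four distinct inference stimuli, two per context
    inf_ids <- sample.int(n, 4)
    inf1 <- c(high = inf_ids[1], low = inf_ids[2])
    inf2 <- c(high = inf_ids[3], low = inf_ids[4])
    for (try in seq_len(max_tries)) {
      v1 <- sample.int(101, n, replace = TRUE) - 1L
      v2 <- sample.int(101, n, replace = TRUE) - 1L
      v1[inf1] <- inference_values[[1]]
      v2[inf2] <- inference_values[[2]]
      if (abs(sum(v1) - sum(v2)) > sum_tol) next
      dv <- c(abs(outer(v1, v1, "-"))[lower.tri(D)],
              abs(outer(v2, v2, "-"))[lower.tri(D)])
      ct <- stats::cor.test(rep(dvec, 2), dv)
      if (ct$p.value > alpha) {
        names(v1) <- names(v2) <- rownames(layout$coords)
        return(list(
          reward_context(1L, v1, inf1),
          reward_context(2L, v2, inf2)
        ))
      }
    }
    stop("make_reward_contexts: no admissible value assignment after ",
         max_tries, " tries; relax alpha or sum_tol")
  })
}

#' Construct a reward context
#' @param context_id 1 or 2.
#' @param values Named integer vector of stimulus values in \[0, 100\].
#' @param inference Named integer vector `c(high = id, low = id)`.
#' @export
reward_context <- function(context_id, values, inference) {
  stopifnot(all(values >= 0), all(values <= 100),
            all(c("high", "low") %in% names(inference)))
  structure(list(context_id = as.integer(context_id),
                 values = as.integer(round(values)) |> stats::setNames(names(values)),
                 inference = inference),
            class = "reward_context")
}

#' Stimuli eligible as choice options (non-inference in either context)
#' @keywords internal
choice_stimuli <- function(contexts, n) {
  setdiff(seq_len(n), unlist(lapply(contexts, function(cc) unname(cc$inference))))
}
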