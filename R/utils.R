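#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a stream-specific sub-seed from a master seed
#'
#' Deterministic, keeps results within 32-bit integer range so the same
#' master seed always yields the same sub-streams.
#' @keywords internal
sub_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483587
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Check that a matrix is symmetric positive semi-definite
#' @keywords internal
assert_psd <- function(K, tol = 1e-10, label = "kernel") {
  if (!isSymmetric(unname(K), tol = 1e-8)) {
    stop(label, " matrix is not symmetric")
  }
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    stop(label, " matrix is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")")
  }
  invisible(TRUE)
}
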