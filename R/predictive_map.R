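#' Learn a successor representation from a visit sequence
#'
#' Temporal-difference learning of the successor matrix M, whose entry
#' (s, s') is the expected discounted number of future visits to s' starting
#' from s. For each consecutive visit pair (s, s') the row of s is updated by
#' `M[s, ] <- M[s, ] + eta * (1_s + gamma * M[s', ] - M[s, ])`.
#'
#' @param visits Integer vector of visited stimulus ids (in visit order).
#' @param n_states Number of stimuli.
#' @param gamma Discount factor in (0, 1); default 0.9.
#' @param eta Learning rate in (0, 1].
#' @param init `"zeros"` (default) or `"identity"` initialisation.
#' @param passes Number of passes over the visit sequence (default 1,
#'   experiential order).
#' @return n x n successor matrix with attributes `gamma` and `eta`.
#' @export
learn_successor <- function(visits, n_states, gamma = 0.9, eta = 0.1,
                            init = c("zeros", "identity"), passes = 1L) {
  init <- match.arg(init)
  if (eta <= 0 || eta > 1) stop("learn_successor: eta must be in (0, 1]")
  if (gamma <= 0 || gamma >= 1) stop("learn_successor: gamma must be in (0, 1)")
  if (length(visits) < 2) stop("learn_successor: need at least 2 visits")
  if (any(visits < 1) || any(visits > n_states)) {
    stop("learn_successor: visit ids outside 1..n_states")
  }
  M <- if (init == "zeros") matrix(0, n_states, n_states) else diag(n_states)
  for (p in seq_len(passes)) {
    for (i in seq_len(length(visits) - 1L)) {
      s <- visits[i]; sp <- visits[i + 1L]
      target <- gamma * M[sp, ]
      target[s] <- target[s] + 1
      M[s, ] <- M[s, ] + eta * (target - M[s, ])
    }
  }
  structure(M, gamma = gamma, eta = eta)
}

#' Invert a successor matrix into a symmetric transition matrix
#'
#' Recovers the one-step transition matrix via `T = (M^-1 - I) / (-gamma)`,
#' clips small negative entries produced by finite-sample M to zero,
#' enforces symmetry by the pairwise maximum of the upper and lower
#' triangles, and (by default) renormalises rows with positive mass to sum
#' to one so that `L = I - T` remains a normalized graph Laplacian.
#'
#' @param M Successor matrix (with a `gamma` attribute, or pass `gamma`).
#' @param gamma Discount used to build M.
#' @param symmetrize Apply pairwise-max symmetrisation (default `TRUE`).
#' @param renormalize Renormalise rows after symmetrisation (default `TRUE`).
#' @param max_condition Reject M with 2-norm condition number above this.
#' @return List of class `transition_matrix`: `T`, Laplacian `L = I - T`,
#'   `symmetrized`, and bookkeeping counts `n_clipped`.
#' @export
successor_to_transition <- function(M, gamma = attr(M, "gamma") %||% 0.9,
                                    symmetrize = TRUE, renormalize = TRUE,
                                    max_condition = 1e10) {
  M <- unclass(as.matrix(M))
  kap <- kappa(M, exact = TRUE)
  if (!is.finite(kap) || kap > max_condition) {
    stop("successor_to_transition: M is ill-conditioned (condition number ",
         format(kap, digits = 3),
         "); consider the count-based estimator count_transitions()")
  }
  Tm <- (solve(M) - diag(nrow(M))) / (-gamma)
  n_clipped <- sum(Tm < 0)
  Tm[Tm < 0] <- 0
  finalize_transition(Tm, symmetrize = symmetrize, renormalize = renormalize,
                      n_clipped = n_clipped)
}

finalize_transition <- function(Tm, symmetrize = TRUE, renormalize = TRUE,
                                n_clipped = 0L) {
  if (symmetrize) Tm <- pmax(Tm, t(Tm))
  if (renormalize) {
    rs <- rowSums(Tm)
    pos <- rs > 0
    Tm[pos, ] <- Tm[pos, , drop = FALSE] / rs[pos]
  }
  structure(list(T = Tm, L = diag(nrow(Tm)) - Tm, symmetrized = symmetrize,
                 n_clipped = n_clipped),
            class = "transition_matrix")
}

#' Count-based transition matrix from a visit sequence
#'
#' Pools the direct transition counts i -> j and j -> i into a symmetric
#' count matrix and normalises rows to transition probabilities. Rows with
#' no observed transitions are left uniform (with a warning).
#'
#' @inheritParams learn_successor
#' @inheritParams successor_to_transition
#' @return A `transition_matrix` (as [successor_to_transition()]).
#' @export
count_transitions <- function(visits, n_states, symmetrize = TRUE,
                              renormalize = TRUE) {
  if (length(visits) < 2) stop("count_transitions: need at least 2 visits")
  C <- matrix(0, n_states, n_states)
  for (i in seq_len(length(visits) - 1L)) {
    C[visits[i], visits[i + 1L]] <- C[visits[i], visits[i + 1L]] + 1
  }
  C <- C + t(C)  # pool directions
  rs <- rowSums(C)
  if (any(rs == 0)) {
    warning("count_transitions: no observed transitions for stimuli ",
            paste(which(rs == 0), collapse = ", "), "; rows left uniform")
    C[rs == 0, ] <- 1 / n_states
  }
  Tm <- C / rowSums(C)
  finalize_transition(Tm, symmetrize = symmetrize, renormalize = renormalize)
}

#' Diffusion kernel on the stimulus transition graph
#'
#' `K = expm(-lambda * L)` with `L = I - T` the normalized graph Laplacian
#' of the symmetrised transition matrix. Computed by symmetric
#' eigendecomposition, which keeps K exactly symmetric and positive
#' semi-definite.
#'
#' @param transition A `transition_matrix` (or a bare symmetric T matrix).
#' @param lambda Non-negative lengthscale; default 1.
#' @return Symmetric PSD kernel matrix with attribute `kind = "predictive"`.
#' @export
diffusion_kernel <- function(transition, lambda = 1) {
  if (lambda < 0) stop("diffusion_kernel: lambda must be non-negative")
  if (inherits(transition, "transition_matrix")) {
    if (!transition$symmetrized) {
      stop("diffusion_kernel: transition matrix must be symmetrised first")
    }
    # row renormalisation after pairwise-max can leave slight asymmetry;
    # the Laplacian uses the symmetric part
    Tm <- transition$T
  } else {
    Tm <- as.matrix(transition)
    if (!isSymmetric(unname(Tm), tol = 1e-8)) {
      stop("diffusion_kernel: transition matrix must be symmetrised first")
    }
  }
  L <- diag(nrow(Tm)) - (Tm + t(Tm)) / 2
  eg <- eigen(L, symmetric = TRUE)
  K <- eg$vectors %*% (exp(-lambda * eg$values) * t(eg$vectors))
  K <- (K + t(K)) / 2
  dimnames(K) <- dimnames(Tm)
  structure(K, kind = "predictive", lambda = lambda)
}

#' Identity kernel (mean tracker)
#'
#' The no-generalisation baseline: each stimulus' value is learned
#' independently.
#' @param n Number of stimuli.
#' @export
identity_kernel <- function(n) {
  structure(diag(n), kind = "identity")
}

#' Average two kernels into a compositional kernel
#'
#' Equal-weight average of the spatial (Gaussian) and predictive (diffusion)
#' kernels, modeling generalisation over both structures jointly.
#'
#' @param K_spatial,K_predictive Kernel matrices of matching dimension.
#' @return `(K_spatial + K_predictive) / 2` with `kind = "compositional"`.
#' @export
compose_kernels <- function(K_spatial, K_predictive) {
  if (!all(dim(K_spatial) == dim(K_predictive))) {
    stop("compose_kernels: dimension mismatch")
  }
  structure((unclass(K_spatial) + unclass(K_predictive)) / 2,
            kind = "compositional")
}
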