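#' Stiefel manifold primitives
#'
#' The compact Stiefel manifold `V(n,p)` is the set of real n x p matrices
#' with orthonormal columns. Pattern matrices of the network model live on
#' it. These helpers provide the projection onto the manifold, Haar-uniform
#' sampling, the random-walk proposal used by the Metropolis kernels, and a
#' projected (retraction-based) gradient ascent step.
#'
#' @name stiefel
NULL

#' Test manifold membership
#'
#' @param X numeric matrix.
#' @param tol tolerance on the entrywise deviation of `t(X) %*% X` from the
#'   identity. Default `1e-8`.
#' @return `TRUE` if `X` has (numerically) orthonormal columns.
#' @export
is_stiefel <- function(X, tol = 1e-8) {
  if (!is.matrix(X) || nrow(X) < ncol(X)) return(FALSE)
  max(abs(crossprod(X) - diag(ncol(X)))) < tol
}

#' Project a matrix onto the Stiefel manifold
#'
#' Computes `U %*% t(V)` from the thin SVD `M = U D V'`, the unique
#' Frobenius-closest point of `V(n,p)` when `M` has full column rank.
#'
#' @param M numeric n x p matrix, `p <= n`, full column rank.
#' @return an n x p matrix with orthonormal columns.
#' @export
project_stiefel <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) < ncol(M)) stop("need p <= n")
  if (!all(is.finite(M))) stop("non-finite entries")
  cpp_project_stiefel(M)
}

#' Haar-uniform sample on the Stiefel manifold
#'
#' Orthonormalizes a standard Gaussian n x p matrix (QR with the sign of the
#' triangular factor's diagonal fixed positive), which yields the uniform
#' (Haar) distribution on `V(n,p)`.
#'
#' @param n,p frame dimensions, `1 <= p <= n`.
#' @param size number of draws.
#' @return a single matrix if `size = 1`, else a list of matrices.
#' @export
rstiefel_uniform <- function(n, p, size = 1) {
  if (p > n || p < 1) stop("need 1 <= p <= n")
  out <- cpp_rstiefel(n, p, size)
  if (size == 1) return(out[, , 1, drop = TRUE])
  lapply(seq_len(size), function(k) out[, , k])
}

#' Projected random-walk proposal
#'
#' Adds `step` times a standard Gaussian matrix to `X` and projects the
#' result back onto the manifold. Used as the (approximately symmetric)
#' Metropolis-Hastings proposal for the pattern matrices.
#'
#' @param X point on `V(n,p)`.
#' @param step nonnegative scalar step size; `step = 0` returns `X`.
#' @return a point on `V(n,p)`.
#' @export
stiefel_propose <- function(X, step) {
  if (step < 0) stop("step must be nonnegative")
  cpp_propose_stiefel(X, step)
}

#' Tangent-space projection of a Euclidean gradient
#'
#' Projects an ambient gradient `G` onto the tangent space of `V(n,p)` at
#' `X`: `G - X sym(X'G)` with `sym` the symmetric part.
#'
#' @param X point on the manifold.
#' @param G ambient n x p gradient.
#' @return tangent matrix at `X`.
#' @export
stiefel_tangent <- function(X, G) {
  S <- crossprod(X, G)
  G - X %*% ((S + t(S)) / 2)
}

#' One Riemannian gradient-ascent step with projection retraction
#'
#' Moves `X` by `step` times the tangent projection of `grad` and retracts
#' onto the manifold with [project_stiefel()]. Callers that need a
#' non-decreasing objective should combine this with backtracking on `step`.
#'
#' @param X point on the manifold.
#' @param grad ambient (Euclidean) gradient of the objective at `X`.
#' @param step positive step size.
#' @return a point on `V(n,p)`.
#' @export
stiefel_ascent_step <- function(X, grad, step) {
  if (!all(is.finite(grad))) stop("non-finite gradient")
  Tg <- stiefel_tangent(X, grad)
  project_stiefel(X + step * Tg)
}
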