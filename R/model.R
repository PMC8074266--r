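#' Model containers and closed-form estimation pieces
#'
#' The generative model for a data set of N symmetric n x n adjacency
#' matrices is
#' \deqn{A^{(k)} = X^{(k)} diag(\lambda^{(k)}) X^{(k)'} + \epsilon^{(k)},}
#' with `X(k) ~ vMF(F)` on `V(n,p)`, `lambda(k) ~ N(mu, sigma_lambda^2 I_p)`
#' and symmetric Gaussian noise with standard deviation `sigma_eps` on the
#' upper triangle (diagonal included), mirrored below. The columns of `F` are
#' constrained orthogonal, so its column norms are the concentration
#' parameters and its Stiefel projection is the pattern mode.
#'
#' @name network-model
NULL

#' Model parameter container
#'
#' @param F n x p vMF parameter with orthogonal columns.
#' @param mu mean pattern-weight (eigenvalue) vector, length p.
#' @param sigma_lambda positive weight standard deviation.
#' @param sigma_eps positive noise standard deviation.
#' @return an object of class `stiefelnet_params`.
#' @export
model_params <- function(F, mu, sigma_lambda, sigma_eps) {
  F <- as.matrix(F)
  p <- ncol(F)
  if (length(mu) != p) stop("mu must have length ncol(F)")
  if (sigma_lambda <= 0 || sigma_eps <= 0) stop("variances must be positive")
  G <- crossprod(F)
  if (max(abs(G - diag(diag(G), p))) > 1e-6 * max(1, max(abs(G))))
    warning("columns of F are not orthogonal within tolerance")
  structure(list(F = F, mu = as.numeric(mu), sigma_lambda = sigma_lambda,
                 sigma_eps = sigma_eps),
            class = "stiefelnet_params")
}

#' @export
print.stiefelnet_params <- function(x, ...) {
  n <- nrow(x$F); p <- ncol(x$F)
  cat("Network pattern model parameters (n =", n, ", p =", p, ")\n")
  cat("  concentrations:", paste(signif(vmf_concentrations(x$F), 4), collapse = " "), "\n")
  cat("  mu:            ", paste(signif(x$mu, 4), collapse = " "), "\n")
  cat("  sigma_lambda:  ", signif(x$sigma_lambda, 4), "\n")
  cat("  sigma_eps:     ", signif(x$sigma_eps, 4), "\n")
  cat("  degrees of freedom:", model_dof(n, p), "\n")
  invisible(x)
}

#' Degrees of freedom of the model
#'
#' `n*p` for the pattern parameter, `p` for the mean weights, plus the two
#' standard deviations.
#'
#' @param n,p dimensions, or an object of class `stiefelnet_params` as `n`.
#' @return integer `n*p + p + 2`.
#' @export
model_dof <- function(n, p = NULL) {
  if (inherits(n, "stiefelnet_params")) {
    p <- ncol(n$F); n <- nrow(n$F)
  }
  n * p + p + 2
}

#' Adjacency data set container
#'
#' @param A an n x n x N array, or a list of symmetric n x n matrices.
#' @param mask optional logical symmetric n x n matrix shared by all
#'   subjects; `FALSE` entries (e.g. an unknown diagonal) are excluded from
#'   all likelihood norms.
#' @return object of class `adjacency_dataset` with elements `A` (array) and
#'   `mask`.
#' @export
adjacency_dataset <- function(A, mask = NULL) {
  if (is.list(A)) A <- simplify2array(A)
  if (length(dim(A)) == 2) A <- array(A, c(dim(A), 1))
  n <- dim(A)[1]
  if (dim(A)[2] != n) stop("matrices must be square")
  for (k in seq_len(dim(A)[3]))
    if (max(abs(A[, , k] - t(A[, , k]))) > 1e-9)
      stop("matrix ", k, " is not symmetric within 1e-9")
  if (!is.null(mask)) {
    mask <- matrix(as.logical(mask), n, n)
    if (!isTRUE(all.equal(mask, t(mask)))) stop("mask must be symmetric")
  }
  structure(list(A = A, mask = mask), class = "adjacency_dataset")
}

#' @export
print.adjacency_dataset <- function(x, ...) {
  d <- dim(x$A)
  cat("Adjacency data set:", d[3], "matrices on", d[1], "nodes")
  if (!is.null(x$mask)) cat(" (", sum(!x$mask), "entries masked )")
  cat("\n")
  invisible(x)
}

n_subjects <- function(dataset) dim(dataset$A)[3]
n_nodes <- function(dataset) dim(dataset$A)[1]
mask_matrix <- function(dataset) {
  if (is.null(dataset$mask)) matrix(0, 1, 1) else (dataset$mask) * 1
}
n_observed <- function(dataset) {
  if (is.null(dataset$mask)) n_nodes(dataset)^2 else sum(dataset$mask)
}

#' Rank-p reconstruction from latent variables
#'
#' @param X n x p matrix with orthonormal columns.
#' @param lam weight vector of length p.
#' @return the symmetric matrix `X diag(lam) X'`, whose nonzero spectrum is
#'   exactly `lam`.
#' @export
reconstruct <- function(X, lam) {
  if (length(lam) != ncol(X)) stop("shape mismatch")
  X %*% (lam * t(X))
}

#' Sample a synthetic data set from the model
#'
#' Pattern matrices are drawn from the vMF distribution by adaptive MCMC,
#' weights from their Gaussian, and noise symmetrically: independent
#' `N(0, sigma_eps^2)` on the upper triangle including the diagonal,
#' mirrored below.
#'
#' @param params `stiefelnet_params`.
#' @param N number of subjects.
#' @param latents optional latent state to reuse (same latent patterns and
#'   weights, fresh noise) -- used to study the effect of the noise level at
#'   fixed latent variables.
#' @param mask optional observation mask stored with the data set.
#' @param burnin burn-in sweeps of the per-subject vMF chain. Each pattern
#'   matrix comes from its own chain so the draws are independent across
#'   subjects.
#' @return list with `dataset` (an [adjacency_dataset()]) and `latents`
#'   (list with `X`: n x p x N array, `lam`: p x N matrix).
#' @export
sample_networks <- function(params, N, latents = NULL, mask = NULL,
                            burnin = 600) {
  n <- nrow(params$F); p <- ncol(params$F)
  if (is.null(latents)) {
    # tune the proposal on one short adaptive chain, then run the N
    # independent chains in compiled code with that step size
    step <- tune_vmf_step(params$F)
    X0 <- array(if (max(abs(params$F)) == 0) rstiefel_uniform(n, p) else
      vmf_mode(params$F), c(n, p, N))
    sw <- cpp_gibbs_sweep(array(0, c(n, n, N)), X0, matrix(0, p, N),
                          array(params$F, c(n, p, 1)),
                          matrix(0, p, 1), 1, 1e8,
                          rep(0L, N), matrix(0, 1, 1), burnin, step, 0, FALSE)
    X <- sw$X
    lam <- matrix(rnorm(p * N, params$mu, params$sigma_lambda), p, N)
  } else {
    X <- latents$X; lam <- latents$lam
    N <- dim(X)[3]
  }
  A <- array(0, c(n, n, N))
  ut <- upper.tri(matrix(0, n, n), diag = TRUE)
  for (k in seq_len(N)) {
    E <- matrix(0, n, n)
    E[ut] <- rnorm(sum(ut), 0, params$sigma_eps)
    E <- E + t(E) - diag(diag(E))
    A[, , k] <- reconstruct(X[, , k], lam[, k]) + E
  }
  list(dataset = adjacency_dataset(A, mask = mask),
       latents = list(X = X, lam = lam))
}

# Short adaptive run to pick a vMF proposal step with ~0.3 acceptance.
tune_vmf_step <- function(F, target = 0.3, n_adapt = 12) {
  n <- nrow(F); p <- ncol(F)
  X <- if (max(abs(F)) == 0) rstiefel_uniform(n, p) else vmf_mode(F)
  ls <- log(0.3)
  for (t in seq_len(n_adapt)) {
    sw <- cpp_gibbs_sweep(array(0, c(n, n, 1)), array(X, c(n, p, 1)),
                          matrix(0, p, 1), array(F, c(n, p, 1)),
                          matrix(0, p, 1), 1, 1e8, 0L, matrix(0, 1, 1),
                          25L, exp(ls), 0, FALSE)
    X <- sw$X[, , 1]
    ls <- kernel_adapt(ls, sw$accept_X, t, target)
  }
  exp(ls)
}

#' Complete-data log-likelihood of one subject
#'
#' Sum of the three terms: Gaussian observation term with full-matrix
#' Frobenius norm and `n^2` entry count (masked entries excluded from both),
#' vMF term `tr(F'X) - log C_{n,p}(F)`, and the Gaussian weight term.
#'
#' @param A symmetric n x n matrix.
#' @param X,lam latent variables of the subject.
#' @param params `stiefelnet_params`.
#' @param mask optional logical matrix of observed entries.
#' @param lognorm optionally precomputed `log C_{n,p}` (saves repeated
#'   saddle-point evaluations in loops).
#' @return scalar log-likelihood.
#' @export
complete_loglik <- function(A, X, lam, params, mask = NULL, lognorm = NULL) {
  n <- nrow(A)
  if (is.null(lognorm))
    lognorm <- vmf_lognorm(vmf_concentrations(params$F), n)
  mm <- if (is.null(mask)) matrix(0, 1, 1) else mask * 1
  n_obs <- if (is.null(mask)) n^2 else sum(mask)
  if (params$sigma_eps <= 0 || params$sigma_lambda <= 0)
    stop("variances must be positive")
  as.numeric(cpp_loglik_vec(array(A, c(n, n, 1)), array(X, c(dim(X), 1)),
                            matrix(lam, ncol = 1), params$F, params$mu,
                            params$sigma_lambda, params$sigma_eps, mm,
                            n_obs)) - lognorm
}

# Vectorized complete log-likelihood over subjects, without the -log C term.
loglik_vec_nolc <- function(dataset, X, lam, params) {
  cpp_loglik_vec(dataset$A, X, lam, params$F, params$mu, params$sigma_lambda,
                 params$sigma_eps, mask_matrix(dataset), n_observed(dataset))
}

#' Sufficient statistics of the model
#'
#' The four averages driving the M-step: mean pattern matrix, mean weights,
#' mean squared weight norm, and mean squared (masked) residual norm.
#'
#' @param dataset an [adjacency_dataset()].
#' @param latents list with `X` (n x p x N) and `lam` (p x N).
#' @return list with `S1` (n x p), `S2` (p), `S3`, `S4`.
#' @export
suff_stats <- function(dataset, latents) {
  N <- n_subjects(dataset)
  S1 <- apply(latents$X, c(1, 2), mean)
  S2 <- rowMeans(latents$lam)
  S3 <- mean(colSums(latents$lam^2))
  mm <- mask_matrix(dataset)
  S4 <- mean(vapply(seq_len(N), function(k)
    cpp_resid_quad(dataset$A[, , k], latents$X[, , k], latents$lam[, k], mm),
    numeric(1)))
  list(S1 = S1, S2 = S2, S3 = S3, S4 = S4)
}

#' Closed-form M-step
#'
#' Maximizes the complete likelihood given sufficient statistics:
#' `mu = S2`, `sigma_lambda^2 = (S3 - ||S2||^2)/p`, `sigma_eps^2 = S4`
#' divided by the number of observed entries (`n^2` without a mask), and `F`
#' from the constrained vMF MLE applied to `S1`.
#'
#' @param S sufficient statistics as returned by [suff_stats()].
#' @param n number of nodes.
#' @param n_obs number of observed entries counted over the full matrix
#'   (default `n^2`).
#' @param method normalizer method for the vMF MLE.
#' @return `stiefelnet_params`.
#' @export
m_step <- function(S, n, n_obs = n^2, method = "saddlepoint", s0 = NULL) {
  p <- length(S$S2)
  mu <- S$S2
  s2l <- (S$S3 - sum(mu^2)) / p
  s2e <- S$S4 / n_obs
  if (s2l < 1e-12) {
    if (s2l < -1e-8) warning("negative weight-variance estimate clipped")
    s2l <- 1e-12
  }
  if (s2e < 1e-12) s2e <- 1e-12
  fit <- vmf_mle(S$S1, orthogonal_columns = TRUE, method = method, s0 = s0)
  model_params(fit$F, mu, sqrt(s2l), sqrt(s2e))
}

#' Fit diagnostics
#'
#' Per-subject relative reconstruction errors, the proportion of total
#' variance captured by the rank-p part, the estimated concentrations, and
#' (optionally) the concentration a uniform sample of the same size would
#' produce after greedy alignment -- the reference level below which a
#' pattern carries no population information.
#'
#' @param dataset an [adjacency_dataset()].
#' @param latents posterior latent summaries (`X`, `lam`).
#' @param params fitted `stiefelnet_params`.
#' @param uniform_baseline if `TRUE`, compute the uniform-concentration
#'   reference by simulation.
#' @param n_uniform number of Haar samples for the reference (default 1000).
#' @return list of diagnostics.
#' @export
model_diagnostics <- function(dataset, latents, params,
                              uniform_baseline = FALSE, n_uniform = 1000) {
  N <- n_subjects(dataset)
  mm <- mask_matrix(dataset)
  rel <- vapply(seq_len(N), function(k) {
    q <- cpp_resid_quad(dataset$A[, , k], latents$X[, , k], latents$lam[, k], mm)
    a2 <- if (is.null(dataset$mask)) sum(dataset$A[, , k]^2) else
      sum((dataset$A[, , k] * dataset$mask)^2)
    sqrt(q / a2)
  }, numeric(1))
  tot <- sum(vapply(seq_len(N), function(k)
    if (is.null(dataset$mask)) sum(dataset$A[, , k]^2) else
      sum((dataset$A[, , k] * dataset$mask)^2), numeric(1)))
  res <- sum(vapply(seq_len(N), function(k)
    cpp_resid_quad(dataset$A[, , k], latents$X[, , k], latents$lam[, k], mm),
    numeric(1)))
  out <- list(relative_error_mean = mean(rel), relative_error_sd = sd(rel),
              relative_error = rel,
              variance_explained = 1 - res / tot,
              concentrations = vmf_concentrations(params$F))
  if (uniform_baseline) {
    n <- n_nodes(dataset); p <- ncol(params$F)
    out$uniform_concentration <- uniform_concentration_baseline(n, p, n_uniform)
  }
  out
}

#' Concentration level of an aligned uniform sample
#'
#' Draws `m` Haar-uniform frames, aligns them to the first by greedy column
#' matching (as the fitting algorithm does), and runs the constrained vMF
#' MLE on their mean. Estimated concentrations at or below this level are
#' indistinguishable from no concentration at all.
#'
#' @param n,p frame dimensions.
#' @param m number of Haar draws.
#' @return vector of p reference concentrations.
#' @export
uniform_concentration_baseline <- function(n, p, m = 1000) {
  Xs <- cpp_rstiefel(n, p, m)
  ref <- Xs[, , 1]
  S1 <- ref
  for (k in 2:m) S1 <- S1 + greedy_match(Xs[, , k], ref)$X
  vmf_mle(S1 / m)$concentrations
}
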