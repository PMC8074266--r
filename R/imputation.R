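#' Missing-edge imputation
#'
#' Given fitted parameters, the weights of unobserved edges of a new network
#' are inferred from the posterior `p(A_miss, X, lambda | A_obs; theta)`:
#' by Gibbs sampling (exact Gaussian conditional for the masked entries, MH
#' kernels for the latents) for the posterior mean and credible intervals,
#' or by coordinate ascent for the maximum a posteriori estimate.
#'
#' @name imputation
NULL

#' Edge observation mask
#'
#' @param observed symmetric logical n x n matrix; `TRUE` marks observed
#'   entries.
#' @return object of class `edge_mask`.
#' @export
edge_mask <- function(observed) {
  observed <- matrix(as.logical(observed), nrow(observed), ncol(observed))
  if (!isTRUE(all.equal(observed, t(observed)))) stop("mask must be symmetric")
  structure(list(observed = observed), class = "edge_mask")
}

#' Random and block masking schemes
#'
#' `mask_random` hides a fraction of the upper-triangle entries (diagonal
#' included) uniformly at random; `mask_block` hides all off-diagonal
#' interactions among the given nodes.
#'
#' @param n number of nodes.
#' @param frac fraction of entries to hide.
#' @param nodes node indices whose mutual edges are hidden.
#' @return an [edge_mask()].
#' @export
mask_random <- function(n, frac = 0.4) {
  ut <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  m <- nrow(ut)
  hide <- ut[sample.int(m, round(frac * m)), , drop = FALSE]
  obs <- matrix(TRUE, n, n)
  obs[hide] <- FALSE
  obs[hide[, 2:1, drop = FALSE]] <- FALSE
  edge_mask(obs)
}

#' @rdname mask_random
#' @export
mask_block <- function(n, nodes) {
  obs <- matrix(TRUE, n, n)
  obs[nodes, nodes] <- FALSE
  diag(obs) <- TRUE
  edge_mask(obs)
}

# 0-based upper-triangle (i <= j) index pairs of the missing entries.
missing_pairs <- function(mask) {
  idx <- which(!mask$observed & upper.tri(mask$observed, diag = TRUE),
               arr.ind = TRUE)
  t(idx) - 1L
}

#' Posterior sampling of masked edge weights
#'
#' Gibbs chain over `(A_miss, X, lambda)`: masked entries are redrawn from
#' their exact Gaussian conditional given the latents, the latents move with
#' the same MH kernels as the fitting chain against the full-matrix
#' likelihood (current imputations included). Step sizes adapt during
#' burn-in.
#'
#' @param A_obs symmetric matrix; masked entries may hold any value.
#' @param mask an [edge_mask()].
#' @param params fitted [model_params()].
#' @param n_sweeps,burnin chain length and burn-in (defaults 2000 / 500).
#' @param mh_per_sweep MH updates of (X, lambda) per Gibbs sweep (default 4).
#' @param thin keep one sweep in `thin` after burn-in.
#' @param level credible-interval level (default 0.95).
#' @param fix_latents keep `(X, lambda)` clamped at their initial values
#'   (used to validate the exact conditional against closed form).
#' @param init optional list with starting `X` and `lam`.
#' @return list with the posterior `mean` matrix (observed entries copied
#'   from `A_obs`), `lower`/`upper` interval matrices, the raw `draws`
#'   (missing entries x kept sweeps), and the missing-pair index matrix.
#' @export
impute_posterior <- function(A_obs, mask, params, n_sweeps = 2000,
                             burnin = 500, mh_per_sweep = 4, thin = 1,
                             level = 0.95, fix_latents = FALSE, init = NULL) {
  n <- nrow(A_obs)
  miss <- missing_pairs(mask)
  out_mean <- A_obs
  if (ncol(miss) == 0)
    return(list(mean = A_obs, lower = A_obs, upper = A_obs,
                draws = matrix(0, 0, 0), missing = miss))
  st <- if (is.null(init)) {
    # start the chain at MAP-refined latents so burn-in is spent exploring
    # the posterior rather than locating it
    mp <- impute_map(A_obs, mask, params, max_iters = 60, tol = 1e-7)
    list(X = mp$X, lam = mp$lam)
  } else init
  res <- cpp_impute_gibbs(A_obs, miss, st$X, st$lam, params$F, params$mu,
                          params$sigma_lambda, params$sigma_eps,
                          n_sweeps, burnin, 0.1, 0.5, 0.3, fix_latents,
                          thin, as.integer(mh_per_sweep))
  mu_d <- rowMeans(res$draws)
  qs <- apply(res$draws, 1, quantile, probs = c((1 - level) / 2,
                                                1 - (1 - level) / 2))
  lower <- A_obs; upper <- A_obs
  for (e in seq_len(ncol(miss))) {
    i <- miss[1, e] + 1; j <- miss[2, e] + 1
    out_mean[i, j] <- out_mean[j, i] <- mu_d[e]
    lower[i, j] <- lower[j, i] <- qs[1, e]
    upper[i, j] <- upper[j, i] <- qs[2, e]
  }
  list(mean = out_mean, lower = lower, upper = upper, draws = res$draws,
       missing = miss)
}

# Starting point: latents from the eigendecomposition of the observed matrix
# with masked entries filled by the population-mode reconstruction.
impute_start <- function(A_obs, mask, params) {
  p <- ncol(params$F)
  A0 <- A_obs
  fill <- reconstruct(vmf_mode(params$F), params$mu)
  A0[!mask$observed] <- fill[!mask$observed]
  e <- eigen(A0, symmetric = TRUE)
  ord <- order(abs(e$values), decreasing = TRUE)[seq_len(p)]
  gm <- greedy_match(e$vectors[, ord, drop = FALSE], vmf_mode(params$F))
  list(X = gm$X, lam = e$values[ord][gm$perm])
}

#' Maximum a posteriori imputation
#'
#' Coordinate ascent on the joint posterior density of
#' `(A_miss, X, lambda)` given the observed entries: the masked-entry update
#' is the exact conditional maximizer (the reconstruction), `lambda` moves
#' by backtracking gradient steps, `X` by backtracking Riemannian ascent.
#' The objective never decreases.
#'
#' @inheritParams impute_posterior
#' @param max_iters iteration cap (default 200).
#' @param tol stop when the relative objective change drops below this
#'   (default 1e-8).
#' @return list with the imputed `mean` matrix, final `X`, `lam`, the
#'   objective `trace`, and `converged`.
#' @export
impute_map <- function(A_obs, mask, params, max_iters = 200, tol = 1e-8) {
  n <- nrow(A_obs)
  miss_l <- !mask$observed
  st <- impute_start(A_obs, mask, params)
  X <- st$X; lam <- st$lam
  A <- A_obs
  R0 <- reconstruct(X, lam)
  A[miss_l] <- R0[miss_l]
  lognorm <- vmf_lognorm(vmf_concentrations(params$F), n)
  objective <- function(A, X, lam)
    complete_loglik(A, X, lam, params, lognorm = lognorm)
  trace <- objective(A, X, lam)
  converged <- FALSE
  for (it in seq_len(max_iters)) {
    # lambda: backtracking gradient ascent (a few steps)
    for (s in 1:3) {
      R <- A - reconstruct(X, lam)
      g <- (1 / params$sigma_eps^2) * diag(crossprod(X, R %*% X)) -
        (lam - params$mu) / params$sigma_lambda^2
      gn <- sqrt(sum(g^2))
      if (gn < 1e-14) break
      step <- min(1, (1 + sqrt(sum(lam^2))) / gn)  # bounded first move
      f0 <- objective(A, X, lam)
      repeat {
        ln <- lam + step * g
        if (objective(A, X, ln) >= f0 || step < 1e-14) break
        step <- step / 2
      }
      if (step >= 1e-14) lam <- lam + step * g
    }
    # X: a few backtracking Riemannian ascent moves
    for (s in 1:3)
      X <- ascend_X_once(A, X, lam, params$F, params$sigma_eps, step0 = 1e-2,
                         max_halvings = 20)
    # masked entries: exact maximizer of their Gaussian conditional
    R <- reconstruct(X, lam)
    A[miss_l] <- R[miss_l]
    f <- objective(A, X, lam)
    trace <- c(trace, f)
    if (abs(f - trace[length(trace) - 1]) <=
        tol * (abs(f) + 1e-12)) {
      converged <- TRUE
      break
    }
  }
  list(mean = A, X = X, lam = lam, trace = trace, converged = converged)
}

#' Mean-sample baseline imputer
#'
#' The arithmetic mean of the training matrices, the base reference for
#' missing-data imputation.
#'
#' @param dataset an [adjacency_dataset()].
#' @return symmetric n x n matrix.
#' @export
baseline_mean_impute <- function(dataset) {
  apply(dataset$A, c(1, 2), mean)
}

#' Low-rank truncation baseline
#'
#' Sets masked entries to zero and keeps the `p` dominant (by absolute
#' value) eigenpairs.
#'
#' @param A symmetric matrix with masked entries set to zero.
#' @param p target rank.
#' @return symmetric matrix of rank at most `p`.
#' @export
baseline_lowrank_truncate <- function(A, p) {
  e <- eigen(A, symmetric = TRUE)
  ord <- order(abs(e$values), decreasing = TRUE)[seq_len(min(p, nrow(A)))]
  reconstruct(e$vectors[, ord, drop = FALSE], e$values[ord])
}

#' Relative RMSE over masked entries
#'
#' Frobenius norm of the estimation error restricted to the masked entries,
#' divided by the norm of the truth on the same entries.
#'
#' @param estimate,truth symmetric matrices.
#' @param mask an [edge_mask()]; the error is evaluated on its `FALSE`
#'   (unobserved) entries.
#' @return scalar relative error (1 means an error as large as the truth).
#' @export
masked_rrmse <- function(estimate, truth, mask) {
  m <- !mask$observed
  denom <- sqrt(sum(truth[m]^2))
  if (denom == 0) stop("truth has zero norm on the masked entries")
  sqrt(sum((estimate[m] - truth[m])^2)) / denom
}

#' Calibrate the noise level to a target relative perturbation
#'
#' Finds `sigma_eps` such that the Monte-Carlo average of
#' `||eps|| / ||lambda . X||` equals the target (the imputation experiments
#' use 25 percent), by bisection.
#'
#' @param params [model_params()] whose `sigma_eps` is ignored.
#' @param target target mean relative difference (default 0.25).
#' @param n_mc Monte-Carlo draws per evaluation (default 400).
#' @return calibrated `sigma_eps` value.
#' @export
calibrate_sigma_eps <- function(params, target = 0.25, n_mc = 400) {
  n <- nrow(params$F); p <- ncol(params$F)
  lam <- matrix(rnorm(p * n_mc, params$mu, params$sigma_lambda), p, n_mc)
  signal <- sqrt(colSums(lam^2))  # ||lambda . X||_F = ||lambda||
  ut_n <- n * (n + 1) / 2
  # one shared set of standardized noise draws keeps the bisection monotone
  E2 <- vapply(seq_len(n_mc), function(k) {
    e <- rnorm(ut_n)
    d <- e[seq_len(n)]          # diagonal slots counted once
    2 * sum(e^2) - sum(d^2)
  }, numeric(1))
  relmean <- function(s) mean(s * sqrt(E2) / signal)
  lo <- 1e-6; hi <- 10 * max(signal) / sqrt(mean(E2))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (relmean(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
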