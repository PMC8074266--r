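#' Mixture of network pattern models
#'
#' Heterogeneous populations are modeled by K copies of the decomposition
#' model: a categorical cluster label picks the component whose vMF
#' parameter, mean weights and variances generate the subject's matrix.
#' Fitting adds a tempered cluster-label resampling step to the Gibbs sweep
#' and runs the M-step per cluster.
#'
#' @name mixture
NULL

#' Mixture parameter container
#'
#' @param components list of K [model_params()] objects with common (n, p).
#' @param pi probability vector of length K.
#' @return object of class `stiefelnet_mixture`.
#' @export
mixture_params <- function(components, pi) {
  K <- length(components)
  if (length(pi) != K) stop("pi must have one entry per component")
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8) stop("pi must be a probability vector")
  dims <- vapply(components, function(th) dim(th$F), numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("components must share dimensions")
  structure(list(components = components, pi = as.numeric(pi)),
            class = "stiefelnet_mixture")
}

#' Sample from the mixture model
#'
#' Ancestral sampling: labels from `Categorical(pi)`, then latents and
#' matrices from the selected component.
#'
#' @param mix a [mixture_params()] object.
#' @param N number of subjects.
#' @param ... passed to [sample_networks()] (MCMC controls).
#' @return list with `dataset`, `latents` and integer `labels`.
#' @export
sample_mixture <- function(mix, N, ...) {
  K <- length(mix$components)
  labels <- sample.int(K, N, replace = TRUE, prob = mix$pi)
  n <- nrow(mix$components[[1]]$F); p <- ncol(mix$components[[1]]$F)
  X <- array(0, c(n, p, N)); lam <- matrix(0, p, N)
  A <- array(0, c(n, n, N))
  for (c in seq_len(K)) {
    idx <- which(labels == c)
    if (length(idx) == 0) next
    sim <- sample_networks(mix$components[[c]], length(idx), ...)
    X[, , idx] <- sim$latents$X
    lam[, idx] <- sim$latents$lam
    A[, , idx] <- sim$dataset$A
  }
  list(dataset = adjacency_dataset(A), latents = list(X = X, lam = lam),
       labels = labels)
}

#' Tempering schedule for cluster-label sampling
#'
#' `T_t = 1 + 50 / t^0.6`; sampled cluster probabilities are raised to
#' `1/T_t` and renormalized, which flattens the conditional early on and
#' lets subjects move between clusters.
#'
#' @param t iteration index, `t >= 1`.
#' @return temperature value (51 at `t = 1`, decreasing to 1).
#' @export
mixture_temperature <- function(t) 1 + 50 / t^0.6

#' Posterior cluster probabilities of one subject
#'
#' Proportional to `pi_c` times the complete likelihood under component
#' `theta_c`. The vMF normalizing constants do not cancel across clusters
#' and are evaluated per component.
#'
#' @param A subject matrix.
#' @param X,lam the subject's latent variables.
#' @param mix a [mixture_params()] object.
#' @param mask optional observation mask.
#' @return vector of K probabilities summing to 1.
#' @export
cluster_posterior <- function(A, X, lam, mix, mask = NULL) {
  K <- length(mix$components)
  ll <- vapply(seq_len(K), function(c)
    complete_loglik(A, X, lam, mix$components[[c]], mask = mask) +
      log(mix$pi[c]), numeric(1))
  if (all(!is.finite(ll))) {
    warning("all cluster weights vanished; returning uniform probabilities")
    return(rep(1 / K, K))
  }
  w <- exp(ll - max(ll))
  w / sum(w)
}

# K-Means initialization on vectorized upper triangles (diagonal included),
# with multiple restarts under a fixed sub-seed so the labeling is stable.
kmeans_labels <- function(dataset, K, nstart = 10) {
  n <- n_nodes(dataset); N <- n_subjects(dataset)
  ut <- upper.tri(matrix(0, n, n), diag = TRUE)
  V <- t(apply(dataset$A, 3, function(M) M[ut]))
  km <- kmeans(V, centers = K, nstart = nstart, iter.max = 100)
  as.integer(km$cluster)
}

#' Fit the mixture model by tempered MCMC-SAEM
#'
#' Cluster labels are initialized by K-Means on vectorized upper triangles,
#' each component by the spectral procedure on its members. The main loop
#' resamples labels from tempered posterior probabilities, sweeps the latent
#' variables with the component-specific kernels, accumulates per-cluster
#' sufficient statistics, and applies the M-step per cluster; component vMF
#' parameters are mutually aligned by greedy matching every five iterations.
#'
#' @param dataset an [adjacency_dataset()].
#' @param p number of patterns.
#' @param K number of clusters.
#' @param config a [saem_config()].
#' @return object of class `stiefelnet_mixture_fit` with `params` (a
#'   [mixture_params()]), MAP `labels`, `responsibilities`, `posterior`
#'   latent summaries, and `traces` per component.
#' @export
fit_network_mixture <- function(dataset, p, K, config = saem_config()) {
  res <- saem_engine(dataset, p, K = K, config = config)
  structure(list(params = mixture_params(res$params, res$pi / sum(res$pi)),
                 labels = apply(res$responsibilities, 1, which.max),
                 responsibilities = res$responsibilities,
                 latents = res$latents, posterior = res$posterior,
                 traces = res$traces, accept = res$accept, config = config),
            class = "stiefelnet_mixture_fit")
}

#' @export
print.stiefelnet_mixture_fit <- function(x, ...) {
  K <- length(x$params$components)
  cat("Tempered mixture MCMC-SAEM fit,", K, "components\n")
  cat("  pi:", paste(signif(x$params$pi, 3), collapse = " "), "\n")
  cat("  cluster sizes:", paste(tabulate(x$labels, K), collapse = " "), "\n")
  invisible(x)
}

#' Best-permutation label accuracy
#'
#' Fraction of agreeing labels maximized over all relabelings of the
#' predicted clusters: exhaustive over the `K!` permutations for `K <= 8`,
#' a greedy-then-exchange assignment heuristic (optimal for the vast
#' majority of confusion tables) beyond.
#'
#' @param truth,predicted integer label vectors of equal length.
#' @return accuracy in `[0, 1]`.
#' @export
label_accuracy <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stop("length mismatch")
  levs <- sort(unique(c(truth, predicted)))
  K <- length(levs)
  Ct <- table(factor(truth, levels = levs), factor(predicted, levels = levs))
  if (K <= 8) {
    perms <- permutations_of(K)
    best <- 0
    for (i in seq_len(nrow(perms))) {
      agr <- sum(Ct[cbind(perms[i, ], seq_len(K))])
      if (agr > best) best <- agr
    }
    return(best / length(truth))
  }
  # greedy assignment with pairwise exchange improvement
  assign <- integer(K)
  Cw <- Ct
  for (s in seq_len(K)) {
    ij <- arrayInd(which.max(Cw), dim(Cw))
    assign[ij[2]] <- ij[1]
    Cw[ij[1], ] <- -1; Cw[, ij[2]] <- -1
  }
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (a in 1:(K - 1)) for (b in (a + 1):K) {
      cur <- Ct[assign[a], a] + Ct[assign[b], b]
      alt <- Ct[assign[b], a] + Ct[assign[a], b]
      if (alt > cur) {
        tmp <- assign[a]; assign[a] <- assign[b]; assign[b] <- tmp
        improved <- TRUE
      }
    }
  }
  sum(Ct[cbind(assign, seq_len(K))]) / length(truth)
}

# All permutations of 1..K as rows (K small).
permutations_of <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(K - 1)
  do.call(rbind, lapply(seq_len(K), function(i) {
    rest <- setdiff(seq_len(K), i)
    cbind(i, matrix(rest[sub], nrow(sub), K - 1))
  }))
}
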