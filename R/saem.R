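#' MCMC-SAEM estimation
#'
#' Maximum-likelihood estimation of the network pattern model by stochastic
#' approximation EM with a Metropolis-within-Gibbs E-step. Each iteration
#' runs a few MH steps per subject on `(X, lambda)`, re-aligns the sampled
#' patterns to the current mode by greedy column matching (early iterations
#' only, against permutation/sign non-identifiability), updates the running
#' sufficient statistics with a Robbins-Monro weight, and applies the
#' closed-form M-step.
#'
#' @name saem
NULL

#' SAEM configuration
#'
#' @param n_iterations number of SAEM iterations `T`.
#' @param mcmc_steps MH steps per subject per SAEM iteration (default 20).
#' @param match_every greedy column matching every this many iterations
#'   (default 5).
#' @param match_fraction matching is active for the first
#'   `match_fraction * T` iterations (default 1/3).
#' @param n_hybrid hybrid start-up iterations in which the X move is a
#'   Riemannian gradient-ascent step instead of MH (default 10).
#' @param target_accept target MH acceptance rate for step-size adaptation
#'   (default 0.3).
#' @param init `"spectral"` (leading eigenpairs, the default) or `"random"`.
#' @param mode_moves include discrete transposition/sign-flip MH moves in
#'   the latent kernel (default `TRUE`). Together with the greedy matching
#'   step these constitute the sampler's handling of the permutation/sign
#'   non-identifiability; disabling both isolates its effect.
#' @param step_X0,step_lam0 initial MH step sizes (adapted thereafter).
#' @param store_traces keep per-iteration parameter traces (default `TRUE`).
#' @param seed optional integer seed applied at the start of the fit.
#' @return list of class `saem_config`.
#' @export
saem_config <- function(n_iterations = 100, mcmc_steps = 20, match_every = 5,
                        match_fraction = 1 / 3, n_hybrid = 10,
                        target_accept = 0.3, init = c("spectral", "random"),
                        step_X0 = 0.1, step_lam0 = 0.5, store_traces = TRUE,
                        mode_moves = TRUE, seed = NULL) {
  init <- match.arg(init)
  stopifnot(n_iterations >= 1, mcmc_steps >= 1, match_every >= 1,
            target_accept > 0, target_accept < 1)
  structure(list(n_iterations = n_iterations, mcmc_steps = mcmc_steps,
                 match_every = match_every, match_fraction = match_fraction,
                 n_hybrid = n_hybrid, target_accept = target_accept,
                 init = init, step_X0 = step_X0, step_lam0 = step_lam0,
                 store_traces = store_traces, mode_moves = mode_moves,
                 seed = seed),
            class = "saem_config")
}

#' Stochastic-approximation weight schedule
#'
#' `1` for the first half of the iterations, then decreasing as
#' `(t - floor(T/2))^-0.6`, which satisfies the usual Robbins-Monro
#' conditions on the tail.
#'
#' @param t iteration index, `1 <= t <= T`.
#' @param T total number of iterations.
#' @return scalar weight in (0, 1].
#' @export
sa_weight <- function(t, T) {
  half <- floor(T / 2)
  if (t <= half) 1 else (t - half)^(-0.6)
}

#' Step-size adaptation rule
#'
#' Increments the log step size by `+1/(2 t^0.6)` when the observed
#' acceptance proportion exceeds the target, `-1/(2 t^0.6)` otherwise
#' (ties decrease).
#'
#' @param log_step current log step size.
#' @param accept_rate observed acceptance proportion since last adaptation.
#' @param t adaptation index, `t >= 1`.
#' @param target target acceptance rate.
#' @return updated log step size.
#' @export
kernel_adapt <- function(log_step, accept_rate, t, target = 0.3) {
  log_step + (if (accept_rate > target) 1 else -1) / (2 * t^0.6)
}

#' Greedy column matching
#'
#' Aligns the columns of `X` to those of a reference `M` (typically the
#' current vMF mode): repeatedly picks the unassigned pair `(i, j)` with the
#' largest absolute inner product `|<m_i, x_j>|` (ties broken by the first
#' occurrence in column-major order), assigns column `j` of `X` to slot `i`
#' with the sign of the inner product, and removes both from play.
#'
#' @param X,M matrices with the same dimensions; `M` is the reference.
#' @return list with `perm` (slot i takes original column `perm[i]`),
#'   `signs`, and `X` (the re-ordered, sign-corrected matrix).
#' @export
greedy_match <- function(X, M) {
  if (!all(dim(X) == dim(M))) stop("dimension mismatch")
  p <- ncol(X)
  C <- crossprod(M, X)
  W <- abs(C)
  perm <- integer(p)
  sgn <- numeric(p)
  for (s in seq_len(p)) {
    ij <- arrayInd(which.max(W), dim(W))
    i <- ij[1]; j <- ij[2]
    perm[i] <- j
    sgn[i] <- if (C[i, j] < 0) -1 else 1
    W[i, ] <- -Inf
    W[, j] <- -Inf
  }
  list(perm = perm, signs = sgn,
       X = sweep(X[, perm, drop = FALSE], 2, sgn, `*`))
}

#' One Metropolis-within-Gibbs sweep (single-model case)
#'
#' Runs `n_steps` alternating MH updates of `X` (projected Gaussian walk)
#' and `lambda` (Gaussian walk) for every subject, targeting
#' `p(X, lambda | A; theta)`.
#'
#' @param dataset an [adjacency_dataset()].
#' @param latents list with `X` (n x p x N) and `lam` (p x N).
#' @param params `stiefelnet_params`.
#' @param n_steps MH steps per subject.
#' @param step_X,step_lam proposal step sizes.
#' @return list with updated `latents` and acceptance rates `accept_X`,
#'   `accept_lam`.
#' @export
gibbs_sweep <- function(dataset, latents, params, n_steps = 1,
                        step_X = 0.1, step_lam = 0.5, mode_moves = TRUE) {
  sw <- cpp_gibbs_sweep(dataset$A, latents$X, latents$lam,
                        array(params$F, c(dim(params$F), 1)),
                        matrix(params$mu, ncol = 1), params$sigma_lambda,
                        params$sigma_eps,
                        rep(0L, n_subjects(dataset)), mask_matrix(dataset),
                        n_steps, step_X, step_lam, mode_moves)
  list(latents = list(X = sw$X, lam = sw$lam),
       accept_X = sw$accept_X, accept_lam = sw$accept_lam)
}

# Spectral initialization: leading |eigenvalue| pairs of each matrix, aligned
# within each cluster to its first member.
saem_init_latents <- function(dataset, p, labels = NULL) {
  n <- n_nodes(dataset); N <- n_subjects(dataset)
  if (n < p) stop("need p <= number of nodes")
  if (is.null(labels)) labels <- rep(1L, N)
  X <- array(0, c(n, p, N))
  lam <- matrix(0, p, N)
  for (k in seq_len(N)) {
    e <- eigen(dataset$A[, , k], symmetric = TRUE)
    ord <- order(abs(e$values), decreasing = TRUE)[seq_len(p)]
    X[, , k] <- e$vectors[, ord, drop = FALSE]
    lam[, k] <- e$values[ord]
  }
  for (c in unique(labels)) {
    idx <- which(labels == c)
    ref <- X[, , idx[1]]
    for (k in idx[-1]) {
      gm <- greedy_match(X[, , k], ref)
      X[, , k] <- gm$X
      lam[, k] <- lam[gm$perm, k]
    }
  }
  list(X = X, lam = lam)
}

#' Spectral initialization
#'
#' Takes the `p` leading eigenpairs (by absolute eigenvalue) of each
#' adjacency matrix, aligns all pattern matrices to the first subject by
#' greedy column matching, and produces starting parameters from the M-step
#' applied to the resulting statistics.
#'
#' @param dataset an [adjacency_dataset()].
#' @param p number of patterns.
#' @return list with `params` and `latents`.
#' @export
saem_init <- function(dataset, p) {
  latents <- saem_init_latents(dataset, p)
  S <- suff_stats(dataset, latents)
  list(params = m_step(S, n_nodes(dataset), n_observed(dataset)),
       latents = latents)
}

# Gradient of the (X-dependent part of the) complete log-likelihood and one
# backtracking Riemannian ascent move, used in the hybrid start-up phase and
# for MAP imputation.
ascend_X_once <- function(A, X, lam, F, sigma_eps, mask = NULL,
                          step0 = 1e-2, max_halvings = 12) {
  objfun <- function(X) {
    R <- A - reconstruct(X, lam)
    if (!is.null(mask)) R <- R * mask
    -sum(R^2) / (2 * sigma_eps^2) + sum(F * X)
  }
  R <- A - reconstruct(X, lam)
  if (!is.null(mask)) R <- R * mask
  grad <- (2 / sigma_eps^2) * sweep(R %*% X, 2, lam, `*`) + F
  # scale the trial step so the first move has bounded manifold magnitude
  # regardless of the likelihood precision (gradients scale as 1/sigma_eps^2)
  tg <- stiefel_tangent(X, grad)
  gn <- sqrt(sum(tg^2))
  if (gn < 1e-14) return(X)
  f0 <- objfun(X)
  step <- min(step0, 0.5 / gn)
  for (h in seq_len(max_halvings)) {
    Xn <- stiefel_ascent_step(X, grad, step)
    if (objfun(Xn) >= f0) return(Xn)
    step <- step / 2
  }
  X
}

#' Fit the network pattern model by MCMC-SAEM
#'
#' Spectral initialization, a short hybrid phase where the X update is a
#' Riemannian gradient-ascent step, then the main SAEM loop: MH-within-Gibbs
#' sweep, greedy column matching against the current mode (first third of
#' the iterations), stochastic update of the sufficient statistics, and
#' closed-form M-step with the saddle-point vMF MLE. Step sizes adapt toward
#' the target acceptance rate.
#'
#' @param dataset an [adjacency_dataset()].
#' @param p number of rank-one patterns.
#' @param config a [saem_config()].
#' @return object of class `stiefelnet_fit`: fitted `params`, final MCMC
#'   `latents`, `posterior` summaries (per-subject projected mean pattern
#'   and mean weights over the second half of the iterations), `traces`, and
#'   acceptance diagnostics.
#' @export
fit_network_model <- function(dataset, p, config = saem_config()) {
  res <- saem_engine(dataset, p, K = 1, config = config)
  structure(list(params = res$params[[1]], latents = res$latents,
                 posterior = res$posterior, traces = res$traces[[1]],
                 accept = res$accept, config = config),
            class = "stiefelnet_fit")
}

#' @export
print.stiefelnet_fit <- function(x, ...) {
  cat("MCMC-SAEM fit\n")
  print(x$params)
  invisible(x)
}

# Shared SAEM engine for the single model (K = 1) and the mixture (K > 1).
# For K = 1 no cluster-label RNG is consumed, so the two paths coincide
# draw-for-draw under the same seed.
saem_engine <- function(dataset, p, K, config, verbose = FALSE) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- n_nodes(dataset); N <- n_subjects(dataset)
  n_obs <- n_observed(dataset)
  mm <- mask_matrix(dataset)
  T_iter <- config$n_iterations

  # --- initialization -------------------------------------------------------
  labels <- if (K > 1) kmeans_labels(dataset, K) else rep(1L, N)
  if (config$init == "spectral") {
    latents <- saem_init_latents(dataset, p, labels)
  } else {
    X <- array(0, c(n, p, N))
    for (k in seq_len(N)) X[, , k] <- rstiefel_uniform(n, p)
    latents <- list(X = X, lam = matrix(rnorm(p * N), p, N))
  }
  cluster_stats <- function(idx) {
    sub <- list(A = dataset$A[, , idx, drop = FALSE], mask = dataset$mask)
    class(sub) <- "adjacency_dataset"
    suff_stats(sub, list(X = latents$X[, , idx, drop = FALSE],
                         lam = latents$lam[, idx, drop = FALSE]))
  }
  Sbar <- lapply(seq_len(K), function(c) cluster_stats(which(labels == c)))
  params <- lapply(Sbar, m_step, n = n, n_obs = n_obs)
  pi_hat <- tabulate(labels, K) / N
  logC <- vapply(params, function(th)
    vmf_lognorm(vmf_concentrations(th$F), n), numeric(1))

  lsX <- log(config$step_X0); lsL <- log(config$step_lam0)
  pack <- function() list(
    F = array(unlist(lapply(params, `[[`, "F")), c(n, p, K)),
    mu = matrix(unlist(lapply(params, `[[`, "mu")), p, K),
    sl = vapply(params, `[[`, numeric(1), "sigma_lambda"),
    se = vapply(params, `[[`, numeric(1), "sigma_eps"))

  update_stats <- function(alpha) {
    min_members <- if (K > 1) max(2, ceiling(0.01 * N)) else 0
    for (c in seq_len(K)) {
      idx <- which(labels == c)
      # (near-)empty cluster: freeze its statistics -- a handful of members
      # cannot estimate (F, mu, sigma) and a drifting estimate would kill
      # the component for good during the hot tempering phase
      if (length(idx) < min_members) next
      S <- cluster_stats(idx)
      Sbar[[c]] <<- list(S1 = (1 - alpha) * Sbar[[c]]$S1 + alpha * S$S1,
                         S2 = (1 - alpha) * Sbar[[c]]$S2 + alpha * S$S2,
                         S3 = (1 - alpha) * Sbar[[c]]$S3 + alpha * S$S3,
                         S4 = (1 - alpha) * Sbar[[c]]$S4 + alpha * S$S4)
    }
    pi_hat <<- (1 - alpha) * pi_hat + alpha * (tabulate(labels, K) / N)
  }
  do_m_step <- function() {
    params <<- lapply(seq_len(K), function(c)
      m_step(Sbar[[c]], n = n, n_obs = n_obs,
             s0 = vmf_concentrations(params[[c]]$F)))
    for (th in params)
      if (!all(is.finite(th$F)) || !all(is.finite(th$mu)))
        stop("non-finite parameter update; aborting (see traces)")
    logC <<- vapply(params, function(th)
      vmf_lognorm(vmf_concentrations(th$F), n), numeric(1))
  }

  # --- hybrid gradient phase ------------------------------------------------
  for (h in seq_len(config$n_hybrid)) {
    pp <- pack()
    sw <- cpp_gibbs_sweep(dataset$A, latents$X, latents$lam, pp$F, pp$mu,
                          pp$sl, pp$se, labels - 1L, mm,
                          config$mcmc_steps, 0, exp(lsL),
                          isTRUE(config$mode_moves))
    latents$X <- sw$X; latents$lam <- sw$lam
    for (k in seq_len(N)) {
      c <- labels[k]
      latents$X[, , k] <- ascend_X_once(dataset$A[, , k], latents$X[, , k],
                                        latents$lam[, k], params[[c]]$F,
                                        params[[c]]$sigma_eps, dataset$mask)
    }
    update_stats(1)
    do_m_step()
  }

  # --- main SAEM loop -------------------------------------------------------
  empty_warned <- FALSE
  traces <- if (config$store_traces)
    lapply(seq_len(K), function(c)
      matrix(NA_real_, T_iter, 2 * p + 4,
             dimnames = list(NULL, c(paste0("mu", seq_len(p)),
                                     paste0("conc", seq_len(p)),
                                     "sigma_lambda", "sigma_eps",
                                     "accept_X", "accept_lam"))))
  resp <- matrix(1, N, K)
  Xsum <- array(0, c(n, p, N)); lamsum <- matrix(0, p, N); n_sum <- 0
  half <- floor(T_iter / 2)

  for (t in seq_len(T_iter)) {
    # cluster labels (mixture only): sample from the tempered conditional
    # (probabilities raised to 1/T_t, renormalized); the hot early phase
    # deliberately randomizes assignments so subjects can move between
    # clusters, and structure re-forms by progressive symmetry breaking as
    # the temperature decreases.
    if (K > 1) {
      ll <- matrix(0, N, K)
      for (c in seq_len(K))
        ll[, c] <- cpp_loglik_vec(dataset$A, latents$X, latents$lam,
                                  params[[c]]$F, params[[c]]$mu,
                                  params[[c]]$sigma_lambda,
                                  params[[c]]$sigma_eps, mm, n_obs) -
          logC[c] + log(pmax(pi_hat[c], 1e-300))
      Tt <- mixture_temperature(t)
      lt <- ll / Tt
      lt <- lt - apply(lt, 1, max)
      resp_t <- exp(lt) / rowSums(exp(lt))
      labels <- vapply(seq_len(N), function(k)
        sample.int(K, 1, prob = resp_t[k, ]), integer(1))
      # untempered responsibilities for reporting
      l0 <- ll - apply(ll, 1, max)
      resp <- exp(l0) / rowSums(exp(l0))
      if (!empty_warned && any(tabulate(labels, K) == 0)) {
        warning("empty cluster encountered; freezing its parameters")
        empty_warned <- TRUE
      }
    }

    pp <- pack()
    sw <- cpp_gibbs_sweep(dataset$A, latents$X, latents$lam, pp$F, pp$mu,
                          pp$sl, pp$se, labels - 1L, mm,
                          config$mcmc_steps, exp(lsX), exp(lsL),
                          isTRUE(config$mode_moves))
    latents$X <- sw$X; latents$lam <- sw$lam
    lsX <- kernel_adapt(lsX, sw$accept_X, t, config$target_accept)
    lsL <- kernel_adapt(lsL, sw$accept_lam, t, config$target_accept)

    # greedy matching against the current modes (first third)
    if (t %% config$match_every == 0 && t <= config$match_fraction * T_iter) {
      modes <- lapply(params, function(th) vmf_mode(th$F))
      for (k in seq_len(N)) {
        gm <- greedy_match(latents$X[, , k], modes[[labels[k]]])
        latents$X[, , k] <- gm$X
        latents$lam[, k] <- latents$lam[gm$perm, k]
      }
    }
    # mutual alignment of the component parameters (mixture only)
    if (K > 1 && t %% 5 == 0) {
      mode1 <- vmf_mode(params[[1]]$F)
      for (c in 2:K) {
        gm <- greedy_match(vmf_mode(params[[c]]$F), mode1)
        params[[c]]$F <- sweep(params[[c]]$F[, gm$perm, drop = FALSE], 2,
                               gm$signs, `*`)
        params[[c]]$mu <- params[[c]]$mu[gm$perm]
        Sbar[[c]]$S1 <- sweep(Sbar[[c]]$S1[, gm$perm, drop = FALSE], 2,
                              gm$signs, `*`)
        Sbar[[c]]$S2 <- Sbar[[c]]$S2[gm$perm]
      }
    }

    update_stats(sa_weight(t, T_iter))
    do_m_step()

    if (config$store_traces) for (c in seq_len(K))
      traces[[c]][t, ] <- c(params[[c]]$mu,
                            vmf_concentrations(params[[c]]$F),
                            params[[c]]$sigma_lambda, params[[c]]$sigma_eps,
                            sw$accept_X, sw$accept_lam)
    if (t > half) {
      Xsum <- Xsum + latents$X
      lamsum <- lamsum + latents$lam
      n_sum <- n_sum + 1
    }
    if (verbose && t %% 50 == 0)
      message("iteration ", t, "/", T_iter,
              " accept X ", signif(sw$accept_X, 2),
              " lam ", signif(sw$accept_lam, 2))
  }

  post_X <- array(0, c(n, p, N))
  for (k in seq_len(N)) post_X[, , k] <- project_stiefel(Xsum[, , k] / n_sum)
  list(params = params, pi = pi_hat, labels = labels,
       responsibilities = resp, latents = latents,
       posterior = list(X = post_X, lam = lamsum / n_sum),
       traces = if (config$store_traces) traces,
       accept = list(rate_X = sw$accept_X, rate_lam = sw$accept_lam,
                     step_X = exp(lsX), step_lam = exp(lsL)))
}
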