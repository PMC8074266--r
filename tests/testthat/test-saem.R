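test_that("stochastic-approximation schedule follows the two-phase rule", {
  expect_identical(sa_weight(1, 100), 1)
  expect_identical(sa_weight(50, 100), 1)
  expect_equal(sa_weight(82, 100), 0.125)
  w <- vapply(51:100, sa_weight, numeric(1), T = 100)
  expect_true(all(diff(w) < 0))
})

test_that("step-size adaptation moves the log step by 1/(2 t^0.6)", {
  expect_equal(kernel_adapt(0, 0.5, 1, 0.3), 0.5)
  expect_equal(kernel_adapt(0, 0.1, 1, 0.3), -0.5)
  expect_equal(abs(kernel_adapt(1, 0.9, 32, 0.3) - 1), 0.0625)
  # a tie counts as too low
  expect_equal(kernel_adapt(0, 0.3, 1, 0.3), -0.5)
})

test_that("greedy column matching replays the reference rule", {
  set.seed(30)
  X <- rstiefel_uniform(7, 4)
  gm <- greedy_match(X, X)
  expect_identical(gm$perm, 1:4)
  expect_identical(gm$signs, rep(1, 4))
  # swapped and sign-flipped columns are recovered exactly
  Y <- X[, c(2, 1, 3, 4)]
  Y[, 1] <- -Y[, 1]
  gm2 <- greedy_match(Y, X)
  expect_equal(gm2$X, X)
  expect_identical(gm2$perm, c(2L, 1L, 3L, 4L))
  expect_identical(gm2$signs[2], -1)  # slot 2 took the negated column
  # random cases against the step-by-step reference implementation
  for (r in 1:25) {
    p <- sample(2:6, 1)
    A <- rstiefel_uniform(8, p)
    B <- rstiefel_uniform(8, p)
    got <- greedy_match(A, B)
    ref <- greedy_match_reference(A, B)
    expect_identical(got$perm, ref$perm)
    expect_identical(got$signs, ref$signs)
    expect_equal(got$X, ref$X)
  }
})

test_that("Gibbs sweep holds degenerate posteriors fixed and mixes lambda correctly", {
  set.seed(31)
  n <- 3; p <- 2
  M <- rstiefel_uniform(n, p)
  pars <- model_params(sweep(M, 2, c(15, 6), `*`), c(10, 5), 2, 1e-6)
  X0 <- vmf_mode(pars$F)
  A <- reconstruct(X0, c(10.5, 4.7))
  ds <- adjacency_dataset(array(A, c(n, n, 1)))
  lat <- list(X = array(X0, c(n, p, 1)), lam = matrix(c(10.5, 4.7), p, 1))
  # zero steps: the chain stays put with full acceptance
  sw0 <- gibbs_sweep(ds, lat, pars, n_steps = 5, step_X = 0, step_lam = 0)
  expect_identical(sw0$latents$X, lat$X)
  expect_identical(sw0$accept_X, 1)
  # near-degenerate noise: the chain cannot leave the truth
  sw <- gibbs_sweep(ds, lat, pars, n_steps = 50, step_X = 0.05,
                    step_lam = 0.2)
  expect_lt(norm(sw$latents$X[, , 1] - X0, "F"), 1e-3)
  expect_lt(max(abs(sw$latents$lam - c(10.5, 4.7))), 1e-3)

  # conditional-conjugacy oracle: E[lambda | A] averaged over X samples
  pars2 <- model_params(sweep(M, 2, c(15, 6), `*`), c(10, 5), 2, 0.8)
  A2 <- reconstruct(X0, c(11, 4)) + 0.3
  A2 <- (A2 + t(A2)) / 2
  ds2 <- adjacency_dataset(array(A2, c(n, n, 1)))
  lat2 <- list(X = array(X0, c(n, p, 1)), lam = matrix(pars2$mu, p, 1))
  prec <- 1 / pars2$sigma_eps^2 + 1 / pars2$sigma_lambda^2
  lam_chain <- cond_mean_chain <- NULL
  for (r in 1:4000) {
    sw2 <- gibbs_sweep(ds2, lat2, pars2, n_steps = 2, step_X = 0.15,
                       step_lam = 0.6)
    lat2 <- sw2$latents
    Xs <- lat2$X[, , 1]
    cm <- (diag(crossprod(Xs, A2 %*% Xs)) / pars2$sigma_eps^2 +
             pars2$mu / pars2$sigma_lambda^2) / prec
    lam_chain <- cbind(lam_chain, lat2$lam[, 1])
    cond_mean_chain <- cbind(cond_mean_chain, cm)
  }
  keep <- 501:4000
  for (i in 1:p) {
    se <- sd(lam_chain[i, keep]) / sqrt(effective_size(lam_chain[i, keep]))
    expect_lt(abs(mean(lam_chain[i, keep]) - mean(cond_mean_chain[i, keep])),
              4 * se)
  }
})

test_that("spectral initialization recovers noise-free latent structure", {
  set.seed(32)
  n <- 6; p <- 2; N <- 8
  M <- rstiefel_uniform(n, p)
  truth <- model_params(sweep(M, 2, c(30, 12), `*`), c(9, 4), 1, 1e-9)
  sim <- sample_networks(truth, N)
  ini <- saem_init(sim$dataset, p)
  S <- suff_stats(sim$dataset, ini$latents)
  expect_lt(S$S4, 1e-10)
  # recovered subspaces match the truth up to column matching
  for (k in 1:N) {
    gm <- greedy_match(ini$latents$X[, , k], sim$latents$X[, , k])
    expect_lt(norm(gm$X - sim$latents$X[, , k], "F"), 1e-6)
  }
  # identical matrices align to identical frames
  ds_same <- adjacency_dataset(array(sim$dataset$A[, , 1], c(n, n, 5)))
  ini2 <- stiefelnet:::saem_init_latents(ds_same, p)
  for (k in 2:5)
    expect_equal(ini2$X[, , k], ini2$X[, , 1])
  # low-noise initialization lands near the true mean weights
  truth2 <- model_params(truth$F, truth$mu, 1, 0.05)
  sim2 <- sample_networks(truth2, 40)
  ini3 <- saem_init(sim2$dataset, p)
  expect_lt(max(abs(sort(ini3$params$mu, decreasing = TRUE) -
                      truth2$mu) / truth2$mu), 0.05)
})

test_that("the SAEM fit recovers a degenerate model to high precision", {
  set.seed(33)
  n <- 4; p <- 2; N <- 25
  M <- rstiefel_uniform(n, p)
  truth <- model_params(sweep(M, 2, c(40, 25), `*`), c(12, 6), 1e-9, 1e-9)
  sim <- sample_networks(truth, N)
  fit <- fit_network_model(sim$dataset, p,
                           saem_config(n_iterations = 30, mcmc_steps = 5,
                                       n_hybrid = 2))
  expect_lt(fit$params$sigma_eps, 1e-3)
  gm <- greedy_match(vmf_mode(fit$params$F), vmf_mode(truth$F))
  expect_lt(max(abs(fit$params$mu[gm$perm] - truth$mu)), 0.05)
  # traces finite, posterior summaries on the manifold
  expect_true(all(is.finite(fit$traces)))
  for (k in 1:3) expect_stiefel(fit$posterior$X[, , k])
})

test_that("acceptance rates are adapted toward the target", {
  set.seed(34)
  n <- 5; p <- 2; N <- 30
  M <- rstiefel_uniform(n, p)
  truth <- model_params(sweep(M, 2, c(20, 10), `*`), c(8, 4), 1.5, 0.5)
  sim <- sample_networks(truth, N)
  fit <- fit_network_model(sim$dataset, p,
                           saem_config(n_iterations = 60, mcmc_steps = 10))
  late <- 45:60
  expect_lt(abs(mean(fit$traces[late, "accept_X"]) - 0.3), 0.15)
  expect_lt(abs(mean(fit$traces[late, "accept_lam"]) - 0.3), 0.15)
})
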