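test_that("reconstruction has exactly the prescribed spectrum", {
  set.seed(20)
  X <- diag(5)[, 1:3]
  expect_equal(reconstruct(X, c(0, 0, 0)), matrix(0, 5, 5))
  expect_equal(reconstruct(X, c(4, 2, 1)), diag(c(4, 2, 1, 0, 0)))
  X <- rstiefel_uniform(6, 3)
  lam <- c(5, -2, 1.5)
  R <- reconstruct(X, lam)
  expect_equal(R, t(R))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sort(ev), sort(c(lam, 0, 0, 0)), tolerance = 1e-10)
})

test_that("synthetic generator matches its distributional contract", {
  set.seed(21)
  M <- rstiefel_uniform(3, 2)
  # degenerate case: spectrum of every matrix is exactly mu
  p0 <- model_params(sweep(M, 2, c(25, 10), `*`), c(20, 10), 1e-9, 1e-9)
  sim0 <- sample_networks(p0, 5)
  for (k in 1:5) {
    ev <- eigen(sim0$dataset$A[, , k], symmetric = TRUE)$values
    expect_equal(sort(ev, decreasing = TRUE), c(20, 10, 0), tolerance = 1e-5)
  }
  # weight law of large numbers
  pars <- model_params(sweep(M, 2, c(25, 10), `*`), c(20, 10), 2, 0.1)
  sim <- sample_networks(pars, 2500)
  mu_hat <- rowMeans(sim$latents$lam)
  expect_lt(max(abs(mu_hat - c(20, 10))), 3 * 2 / sqrt(2500))
  # low-noise regime: top eigenvalues of A track the latent weights
  ev2 <- vapply(1:200, function(k)
    sort(eigen(sim$dataset$A[, , k], symmetric = TRUE)$values,
         decreasing = TRUE)[1:2], numeric(2))
  expect_lt(max(abs(ev2 - apply(sim$latents$lam[, 1:200], 2, sort,
                                decreasing = TRUE))), 0.5)
  # vMF draws match the exact first-moment identity (quadrature oracle)
  h <- 1e-4
  m1 <- (vmf_lognorm(c(25 + h, 10), 3, "exact") -
           vmf_lognorm(c(25 - h, 10), 3, "exact")) / (2 * h)
  emp <- mean(vapply(seq_len(2500), function(k)
    sum(vmf_mode(pars$F)[, 1] * sim$latents$X[, 1, k]), numeric(1)))
  expect_lt(abs(emp - m1), 4 * sqrt(1 / 25) / sqrt(2500))
})

test_that("complete log-likelihood identities and gradients hold", {
  set.seed(22)
  n <- 5; p <- 2
  M <- rstiefel_uniform(n, p)
  pars <- model_params(sweep(M, 2, c(8, 4), `*`), c(3, 1), 1.5, 0.7)
  X <- vmf_mode(pars$F)
  A <- reconstruct(X, pars$mu)
  lc <- vmf_lognorm(vmf_concentrations(pars$F), n)
  base <- complete_loglik(A, X, pars$mu, pars)
  # perfect fit at the mode maximizes over data, weights, and patterns
  expect_lt(complete_loglik(A, X, pars$mu + 0.3, pars), base)
  expect_lt(complete_loglik(A + 0.1, X, pars$mu, pars), base)
  expect_lt(complete_loglik(A, rstiefel_uniform(n, p), pars$mu, pars), base)
  # doubling sigma_eps at a perfect fit costs exactly n^2 log 2
  pars2 <- model_params(pars$F, pars$mu, pars$sigma_lambda, 1.4)
  expect_equal(base - complete_loglik(A, X, pars$mu, pars2),
               n^2 * log(2), tolerance = 1e-9)
  # analytic weight gradient against finite differences
  A2 <- A + matrix(rnorm(n * n, 0, 0.3), n, n)
  A2 <- (A2 + t(A2)) / 2
  lam0 <- pars$mu + c(0.5, -0.2)
  g_num <- num_grad(function(l) complete_loglik(A2, X, l, pars, lognorm = lc),
                    lam0)
  R <- A2 - reconstruct(X, lam0)
  g_ana <- (1 / pars$sigma_eps^2) * diag(crossprod(X, R %*% X)) -
    (lam0 - pars$mu) / pars$sigma_lambda^2
  expect_equal(g_num, g_ana, tolerance = 1e-5)
  # masked entries leave both norm and entry count
  mask <- matrix(TRUE, n, n); diag(mask) <- FALSE
  ll_m <- complete_loglik(A2, X, lam0, pars, mask = mask, lognorm = lc)
  Rm <- (A2 - reconstruct(X, lam0)) * mask
  expect_equal(ll_m,
               -sum(Rm^2) / (2 * pars$sigma_eps^2) -
                 sum(mask) * (log(pars$sigma_eps) + log(2 * pi) / 2) +
                 sum(pars$F * X) - lc -
                 sum((lam0 - pars$mu)^2) / (2 * pars$sigma_lambda^2) -
                 p * (log(pars$sigma_lambda) + log(2 * pi) / 2),
               tolerance = 1e-9)
})

test_that("sufficient statistics match their definition", {
  set.seed(23)
  n <- 4; p <- 2; N <- 6
  X <- array(0, c(n, p, N)); lam <- matrix(rnorm(p * N, 5), p, N)
  A <- array(0, c(n, n, N))
  for (k in 1:N) {
    X[, , k] <- rstiefel_uniform(n, p)
    A[, , k] <- reconstruct(X[, , k], lam[, k]) + diag(runif(1), n)
  }
  ds <- adjacency_dataset(A)
  S <- suff_stats(ds, list(X = X, lam = lam))
  expect_equal(S$S1, apply(X, c(1, 2), mean))
  expect_equal(S$S2, rowMeans(lam))
  expect_equal(S$S3, mean(colSums(lam^2)))
  S4_direct <- mean(vapply(1:N, function(k)
    sum((A[, , k] - reconstruct(X[, , k], lam[, k]))^2), numeric(1)))
  expect_equal(S$S4, S4_direct)
  # exact reconstruction: zero residual statistic
  ds0 <- adjacency_dataset(array(reconstruct(X[, , 1], lam[, 1]), c(n, n, 1)))
  S0 <- suff_stats(ds0, list(X = X[, , 1, drop = FALSE],
                             lam = lam[, 1, drop = FALSE]))
  expect_equal(S0$S4, 0)
})

test_that("M-step reproduces closed-form Gaussian estimates and is stationary", {
  set.seed(24)
  n <- 4; p <- 2; N <- 40
  M <- rstiefel_uniform(n, p)
  truth <- model_params(sweep(M, 2, c(20, 9), `*`), c(6, 3), 1.2, 1e-9)
  sim <- sample_networks(truth, N)
  S <- suff_stats(sim$dataset, sim$latents)
  est <- m_step(S, n)
  # Gaussian weight estimates are the (1/N) empirical moments, exactly
  expect_equal(est$mu, rowMeans(sim$latents$lam))
  expect_equal(est$sigma_lambda^2,
               mean((sim$latents$lam - rowMeans(sim$latents$lam))^2),
               tolerance = 1e-9)
  expect_lt(est$sigma_eps, 1e-4)
  # stationarity of the summed complete likelihood at the M-step output
  sim2 <- sample_networks(model_params(truth$F, truth$mu, 1.2, 0.4), N)
  S2 <- suff_stats(sim2$dataset, sim2$latents)
  est2 <- m_step(S2, n)
  lsum <- function(mu, sl, se) {
    pars <- model_params(est2$F, mu, sl, se)
    lc <- vmf_lognorm(vmf_concentrations(est2$F), n)
    sum(vapply(1:N, function(k)
      complete_loglik(sim2$dataset$A[, , k], sim2$latents$X[, , k],
                      sim2$latents$lam[, k], pars, lognorm = lc), numeric(1)))
  }
  f0 <- lsum(est2$mu, est2$sigma_lambda, est2$sigma_eps)
  h <- 1e-4
  for (i in 1:p) {
    e <- replace(numeric(p), i, h)
    expect_lt(abs(lsum(est2$mu + e, est2$sigma_lambda, est2$sigma_eps) -
                    lsum(est2$mu - e, est2$sigma_lambda, est2$sigma_eps)) /
                (2 * h), 1e-3 * N)
  }
  expect_lt(abs(lsum(est2$mu, est2$sigma_lambda + h, est2$sigma_eps) -
                  lsum(est2$mu, est2$sigma_lambda - h, est2$sigma_eps)) /
              (2 * h), 1e-2 * N)
  expect_lt(abs(lsum(est2$mu, est2$sigma_lambda, est2$sigma_eps + h) -
                  lsum(est2$mu, est2$sigma_lambda, est2$sigma_eps - h)) /
              (2 * h), 1e-2 * N)
  # concentration stationarity: the vMF MLE objective has a flat gradient
  sconc <- vmf_concentrations(est2$F)
  Mhat <- vmf_mode(est2$F)
  co <- diag(crossprod(Mhat, S2$S1))
  obj <- function(s) sum(s * co) - vmf_lognorm(s, n)
  g <- num_grad(obj, sconc, h = 1e-3)
  expect_lt(max(abs(g)), 1e-3)
})

test_that("diagnostics report reconstruction quality and variance explained", {
  set.seed(25)
  n <- 5; p <- 2; N <- 4
  X <- array(0, c(n, p, N)); lam <- matrix(rnorm(p * N, 8), p, N)
  A <- array(0, c(n, n, N))
  for (k in 1:N) {
    X[, , k] <- rstiefel_uniform(n, p)
    A[, , k] <- reconstruct(X[, , k], lam[, k])
  }
  ds <- adjacency_dataset(A)
  pars <- model_params(sweep(X[, , 1], 2, c(5, 3), `*`), rowMeans(lam), 1, 1)
  d_exact <- model_diagnostics(ds, list(X = X, lam = lam), pars)
  expect_equal(d_exact$relative_error_mean, 0)
  expect_equal(d_exact$variance_explained, 1)
  d_null <- model_diagnostics(ds, list(X = X, lam = 0 * lam), pars)
  expect_equal(d_null$variance_explained, 0)
  expect_equal(d_null$relative_error_mean, 1)
  # aligned uniform frames still show a nonzero apparent concentration
  u <- uniform_concentration_baseline(8, 2, m = 300)
  expect_true(all(u > 0) && all(u < 8 * 8))
})
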