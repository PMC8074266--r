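test_that("tempering schedule decreases from 51 toward 1", {
  expect_identical(mixture_temperature(1), 51)
  expect_equal(mixture_temperature(32), 7.25)
  expect_lt(mixture_temperature(1e8), 1.01)
  tt <- mixture_temperature(1:100)
  expect_true(all(diff(tt) < 0))
})

test_that("label accuracy maximizes agreement over relabelings", {
  set.seed(40)
  z <- sample.int(4, 400, replace = TRUE)
  expect_identical(label_accuracy(z, z), 1)
  perm <- c(3L, 1L, 4L, 2L)
  expect_identical(label_accuracy(z, perm[z]), 1)
  # random labels agree at about 1/K
  zr <- sample.int(4, 400, replace = TRUE)
  acc <- label_accuracy(z, zr)
  expect_lt(abs(acc - 0.25), 0.1)
  # exhaustive enumeration cross-check on small instances
  brute <- function(truth, pred, K) {
    perms <- stiefelnet:::permutations_of(K)
    max(apply(perms, 1, function(s) mean(s[pred] == truth)))
  }
  for (r in 1:10) {
    K <- sample(2:5, 1)
    zt <- sample.int(K, 60, replace = TRUE)
    zp <- sample.int(K, 60, replace = TRUE)
    expect_equal(label_accuracy(zt, zp), brute(zt, zp, K))
  }
})

test_that("mixture sampling follows the hierarchical law", {
  set.seed(41)
  M <- rstiefel_uniform(4, 2)
  th1 <- model_params(sweep(M, 2, c(30, 15), `*`), c(10, 5), 1, 0.2)
  th2 <- model_params(sweep(M, 2, c(30, 15), `*`), c(-6, 14), 1, 0.2)
  # degenerate weights put everything in one class
  one <- sample_mixture(mixture_params(list(th1, th2), c(1, 0)), 50)
  expect_true(all(one$labels == 1))
  # label frequencies follow pi
  mixed <- sample_mixture(mixture_params(list(th1, th2), c(0.7, 0.3)), 3000)
  expect_lt(abs(mean(mixed$labels == 1) - 0.7),
            3 * sqrt(0.7 * 0.3 / 3000))
})

test_that("cluster posteriors reduce to pi for identical components and match Bayes", {
  set.seed(42)
  M <- rstiefel_uniform(3, 2)
  th <- model_params(sweep(M, 2, c(12, 6), `*`), c(8, 4), 1.5, 0.5)
  mix_same <- mixture_params(list(th, th, th), c(0.5, 0.3, 0.2))
  sim <- sample_networks(th, 1)
  pr <- cluster_posterior(sim$dataset$A[, , 1], sim$latents$X[, , 1],
                          sim$latents$lam[, 1], mix_same)
  expect_equal(pr, c(0.5, 0.3, 0.2), tolerance = 1e-9)
  expect_equal(sum(pr), 1)
  # two distinct components against a direct Bayes computation with exact
  # normalizing constants (p = 2 quadrature)
  th2 <- model_params(sweep(M, 2, c(25, 3), `*`), c(2, 9), 0.8, 0.9)
  mix2 <- mixture_params(list(th, th2), c(0.6, 0.4))
  A <- sim$dataset$A[, , 1]; X <- sim$latents$X[, , 1]
  lam <- sim$latents$lam[, 1]
  manual <- vapply(1:2, function(c) {
    thc <- mix2$components[[c]]
    lc <- vmf_lognorm(vmf_concentrations(thc$F), 3, method = "exact")
    complete_loglik(A, X, lam, thc, lognorm = lc) + log(mix2$pi[c])
  }, numeric(1))
  manual <- exp(manual - max(manual)); manual <- manual / sum(manual)
  got <- cluster_posterior(A, X, lam, mix2)
  expect_equal(got, manual, tolerance = 0.02)
})

test_that("a one-component mixture fit equals the plain fit draw for draw", {
  set.seed(43)
  M <- rstiefel_uniform(4, 2)
  truth <- model_params(sweep(M, 2, c(20, 10), `*`), c(8, 4), 1.5, 0.3)
  sim <- sample_networks(truth, 20)
  cfg <- saem_config(n_iterations = 15, mcmc_steps = 5, n_hybrid = 2,
                     seed = 99)
  fit1 <- fit_network_model(sim$dataset, 2, cfg)
  fitm <- fit_network_mixture(sim$dataset, 2, 1, cfg)
  expect_equal(fitm$params$components[[1]]$F, fit1$params$F)
  expect_equal(fitm$traces[[1]], fit1$traces)
  expect_true(all(fitm$labels == 1))
})

test_that("well-separated clusters are labeled perfectly", {
  set.seed(44)
  M1 <- rstiefel_uniform(6, 2)
  M2 <- project_stiefel(matrix(rnorm(12), 6, 2))
  th1 <- model_params(sweep(M1, 2, c(200, 150), `*`), c(30, 14), 0.5, 0.2)
  th2 <- model_params(sweep(M2, 2, c(200, 150), `*`), c(-20, 55), 0.5, 0.2)
  sim <- sample_mixture(mixture_params(list(th1, th2), c(0.5, 0.5)), 60)
  fit <- fit_network_mixture(sim$dataset, 2, 2,
                             saem_config(n_iterations = 40, mcmc_steps = 5,
                                         n_hybrid = 2))
  expect_identical(label_accuracy(sim$labels, fit$labels), 1)
  expect_true(all(abs(rowSums(fit$responsibilities) - 1) < 1e-9))
})

test_that("cluster information lives in the spectrum, not in Euclidean geometry", {
  set.seed(45)
  preset <- network_preset("cluster-highdim")
  mix <- stiefelnet:::preset_mixture(preset)
  sim <- sample_mixture(mix, 200)
  # K-Means on raw matrices is defeated by pattern wobble
  km <- label_accuracy(sim$labels, stiefelnet:::kmeans_labels(sim$dataset, 4))
  expect_lt(km, 0.8)
  # while the top eigenvalue classifies nearly perfectly
  tops <- vapply(preset$mu, `[`, numeric(1), 1)
  top_ev <- apply(sim$dataset$A, 3, function(M)
    max(eigen(M, symmetric = TRUE, only.values = TRUE)$values))
  rule <- apply(vapply(tops, function(t) abs(top_ev - t),
                       numeric(length(top_ev))), 1, which.min)
  expect_gt(label_accuracy(sim$labels, rule), 0.97)
})

test_that("the mixture fit beats K-Means on heterogeneous small-dimension populations", {
  cs <- run_experiment("cluster-smalldim", seed = 17)
  expect_gt(cs$accuracy, cs$kmeans_accuracy + 0.1)
})
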