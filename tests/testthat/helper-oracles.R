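# Independent reference implementations used as oracles. These deliberately
# avoid the package's own code paths.

# Haar-uniform 2-frames by explicit Gram-Schmidt, vectorized over draws.
# Returns a list of n x 2 matrices.
haar_frames_p2 <- function(n, m) {
  lapply(seq_len(m), function(k) {
    z1 <- rnorm(n); z2 <- rnorm(n)
    x1 <- z1 / sqrt(sum(z1^2))
    z2 <- z2 - x1 * sum(x1 * z2)
    cbind(x1, z2 / sqrt(sum(z2^2)), deparse.level = 0)
  })
}

# Plain replay of the greedy column-matching rule: repeatedly take the
# largest |<m_i, x_j>| among unassigned pairs, first occurrence in
# column-major order on ties.
greedy_match_reference <- function(X, M) {
  p <- ncol(X)
  C <- t(M) %*% X
  W <- abs(C)
  perm <- integer(p); sgn <- numeric(p)
  for (s in seq_len(p)) {
    best <- -Inf; bi <- 0; bj <- 0
    for (j in seq_len(p)) for (i in seq_len(p)) {  # column-major scan
      if (W[i, j] > best) { best <- W[i, j]; bi <- i; bj <- j }
    }
    perm[bi] <- bj
    sgn[bi] <- if (C[bi, bj] < 0) -1 else 1
    W[bi, ] <- -Inf; W[, bj] <- -Inf
  }
  Xa <- X[, perm, drop = FALSE]
  for (i in seq_len(p)) Xa[, i] <- sgn[i] * Xa[, i]
  list(perm = perm, signs = sgn, X = Xa)
}

# Central finite-difference gradient.
num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- replace(numeric(length(x)), i, h)
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

expect_stiefel <- function(X, tol = 1e-8) {
  expect_lt(max(abs(crossprod(X) - diag(ncol(X)))), tol)
}

# Crude autocorrelation-adjusted effective sample size for MCMC output.
effective_size <- function(x, max_lag = 100) {
  n <- length(x)
  x <- x - mean(x)
  v0 <- mean(x^2)
  s <- 0
  for (l in seq_len(max_lag)) {
    r <- mean(x[seq_len(n - l)] * x[(l + 1):n]) / v0
    if (r < 0.05) break
    s <- s + r
  }
  n / (1 + 2 * s)
}
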