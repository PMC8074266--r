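#' Matrix von Mises-Fisher distribution on the Stiefel manifold
#'
#' The vMF (matrix Langevin) distribution on `V(n,p)` has unnormalized
#' density `exp(tr(F'X))` with respect to the normalized invariant measure.
#' Its mode is the Stiefel projection of `F`; when the columns of `F` are
#' orthogonal (the model's constraint) their norms are the concentration
#' parameters: the larger `||f_i||`, the tighter the i-th pattern column
#' clusters around the mode column.
#'
#' @name vmf
NULL

#' Unnormalized vMF log-density
#'
#' @param X point on `V(n,p)`.
#' @param F n x p parameter matrix.
#' @return `sum(F * X)`, i.e. `tr(F'X)`.
#' @export
vmf_logdensity_unnorm <- function(X, F) {
  if (!all(dim(X) == dim(F))) stop("shape mismatch between X and F")
  sum(F * X)
}

#' Mode and concentrations of a vMF parameter
#'
#' @param F n x p parameter matrix with (numerically) orthogonal columns.
#' @return `vmf_mode`: the Stiefel projection of `F`. `vmf_concentrations`:
#'   the column norms of `F`.
#' @export
vmf_mode <- function(F) project_stiefel(F)

#' @rdname vmf_mode
#' @export
vmf_concentrations <- function(F) sqrt(colSums(F^2))

.tri_cache <- new.env(parent = emptyenv())
tri_indices <- function(p) {
  key <- as.character(p)
  if (is.null(.tri_cache[[key]])) .tri_cache[[key]] <- utils::combn(p, 3)
  .tri_cache[[key]]
}

# Gauss-Legendre nodes/weights on [0, 1] (Golub-Welsch).
gauss_legendre01 <- function(k) {
  i <- seq_len(k - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(x = (x[ord] + 1) / 2, w = w[ord] / 2)
}

# log E_{y uniform on S^(m-1)}[exp(k*y1)] -- the sphere vMF constant,
# Gamma(m/2) (2/k)^(m/2-1) I_(m/2-1)(k) on the log scale.
log_c_sphere <- function(kappa, m) {
  small <- kappa < 1e-6
  out <- numeric(length(kappa))
  out[small] <- kappa[small]^2 / (2 * m)
  kk <- kappa[!small]
  out[!small] <- lgamma(m / 2) + (m / 2 - 1) * (log(2) - log(kk)) +
    log(besselI(kk, m / 2 - 1, expon.scaled = TRUE)) + kk
  out
}

# Exact log-normalizer for p = 2 by 2-d quadrature. Conditioning on the first
# column reduces C_{n,2}(s1,s2) to an integral over the first two coordinates
# (a, b) of a uniform point on S^(n-1):
#   C = E[ exp(s1*a) * c_{n-1}(s2*sqrt(1-b^2)) ],
# with c_m the sphere constant above. In polar coordinates a = sin(psi)cos(phi),
# b = sin(psi)sin(phi) the density is smooth (cos^(n-3)psi sin(psi)), so
# Gauss-Legendre in psi and a trapezoid rule in phi converge fast.
log_c_exact_p2 <- function(s, n, k_psi = 80, k_phi = 160) {
  gl <- gauss_legendre01(k_psi)
  psi <- gl$x * (pi / 2)
  wpsi <- gl$w * (pi / 2) * cos(psi)^(n - 3) * sin(psi)
  phi <- (seq_len(k_phi) - 0.5) * (2 * pi / k_phi)
  A <- outer(sin(psi), cos(phi))
  B <- outer(sin(psi), sin(phi))
  G <- matrix(log_c_sphere(s[2] * sqrt(pmax(1 - B^2, 0)), n - 1), nrow = k_psi)
  # log-sum-exp over the grid for numerical safety at large s; the constant
  # phi weight 2*pi/k_phi appears in numerator and denominator alike
  L <- s[1] * A + G + log(wpsi)  # recycle wpsi down columns
  m0 <- max(L)
  (m0 + log(sum(exp(L - m0)))) - log(k_phi) - log(sum(wpsi))
}

# Saddle-point machinery ------------------------------------------------------
#
# C_{n,p}(F) depends on F only through its singular values s. Writing
# C(s) = exp(sum(s^2)/2) f_W^F(I)/f_W^0(I) with W = Y'Y for Y with independent
# N(F_ij, 1) entries (a noncentral Wishart), both densities at the identity are
# approximated by the multivariate saddle-point formula with the standard
# second-order (1+T) correction; the ratio makes C(0) = 1 exact. The cumulant
# generating function K(Theta) = -(n/2) log|I-2Theta| + tr((I-2Theta)^{-1}L)/2
# - tr(L)/2 (L = diag(s^2)) has a diagonal saddle point and sparse higher
# cumulants, so all correction contractions reduce to sums over index pairs
# and triangles.
spa_piece <- function(u, lam, n, order2 = TRUE) {
  p <- length(u)
  cc <- u * lam
  K <- sum((n / 2) * log(u) + lam * u / 2 - lam / 2)
  theta <- (1 - 1 / u) / 2
  h_d <- 2 * n * u^2 + 4 * lam * u^3
  lh <- sum(log(h_d))
  if (p > 1) {
    H_off <- outer(u, u) * (n + outer(cc, cc, "+"))  # h_{jk}, used off-diagonal
    iu <- upper.tri(H_off)
    lh <- lh + sum(log(H_off[iu]))
  }
  d <- p * (p + 1) / 2
  lf1 <- -(d / 2) * log(2 * pi) - lh / 2 + K - sum(theta)
  if (!order2) return(lf1)
  k3_diag <- 8 * u^3 * (n + 3 * cc)
  v <- k3_diag / h_d
  rho4 <- sum(48 * u^4 * (n + 4 * cc) / h_d^2)
  rho23 <- sum(k3_diag^2 / h_d^3)
  if (p > 1) {
    k3_mix <- 2 * outer(u^2, u) * (n + outer(2 * cc, cc, "+"))  # [j,k]: (j),(jk),(jk)
    off <- H_off
    diag(off) <- Inf  # keep self terms out of row/col sums
    v <- v + rowSums(k3_mix / off)
    rho23 <- rho23 + 3 * sum((k3_mix^2 / (h_d * off^2))[row(off) != col(off)])
    k4_pair <- 6 * outer(u^2, u^2) * (n + 2 * outer(cc, cc, "+"))
    rho4 <- rho4 + sum((k4_pair / off^2)[iu])
    k4_LLEE <- 8 * outer(u^3, u) * (n + outer(3 * cc, cc, "+"))
    rho4 <- rho4 + 2 * sum((k4_LLEE / (h_d * off))[row(off) != col(off)])
    # edge pairs (jk),(jl) sharing node j, vectorized over j
    if (p >= 3) {
      amat <- matrix(u, p, p, byrow = TRUE) / off       # a[j,k] = u_k/h_jk
      bmat <- matrix(u * cc, p, p, byrow = TRUE) / off
      ra <- rowSums(amat); ra2 <- rowSums(amat^2)
      rb <- rowSums(bmat); rab <- rowSums(amat * bmat)
      sum_kl <- (n + 2 * cc) * (ra^2 - ra2) / 2 + (ra * rb - rab)
      rho4 <- rho4 + sum(4 * u^2 * sum_kl)
    }
    if (p >= 3) {
      tri <- tri_indices(p)
      j <- tri[1, ]; k <- tri[2, ]; l <- tri[3, ]
      k3_tri <- u[j] * u[k] * u[l] * (n + cc[j] + cc[k] + cc[l])
      rho23 <- rho23 + 6 * sum(k3_tri^2 / (H_off[cbind(j, k)] * H_off[cbind(k, l)] *
                                             H_off[cbind(j, l)]))
    }
  }
  rho13 <- sum(v^2 / h_d)
  Tc <- rho4 / 8 - (3 * rho13 + 2 * rho23) / 24
  # the asymptotic correction is only meaningful while modest; in strongly
  # high-dimensional regimes (|T| ~ 1 or more, e.g. p close to n) the ratio
  # form falls back to the first-order formula
  if (Tc <= -0.9) return(lf1)
  lf1 + log1p(Tc)
}

#' Log of the vMF normalizing constant
#'
#' Returns an approximation of `log C_{n,p}(F)` for a vMF parameter with
#' singular values `s`, with the convention that densities are taken against
#' the normalized invariant measure, so `s = 0` gives exactly 0. The default
#' method is the saddle-point approximation of the noncentral-Wishart density
#' at the identity (ratio form, second-order correction included), accurate
#' to a fraction of a percent on `log C` except for very small `n` (worst
#' case `n = 3`: about 1.5 percent on `C`). `method = "exact"` evaluates the
#' constant by closed form (`p = 1`, Bessel) or deterministic 2-d quadrature
#' (`p = 2`) and errors for larger `p`.
#'
#' @param s vector of `p` nonnegative singular values (concentrations when
#'   the columns of `F` are orthogonal).
#' @param n ambient dimension, `n >= length(s)`.
#' @param method `"saddlepoint"` (default) or `"exact"` (p <= 2 only).
#' @param order2 include the second-order correction (default `TRUE`).
#' @return scalar `log C_{n,p}`.
#' @export
vmf_lognorm <- function(s, n, method = c("saddlepoint", "exact"), order2 = TRUE) {
  method <- match.arg(method)
  s <- as.numeric(s)
  if (any(s < 0)) stop("negative concentration values")
  if (any(!is.finite(s))) stop("non-finite concentration values")
  p <- length(s)
  if (n < p) stop("need n >= p")
  if (all(s == 0)) return(0)
  if (method == "exact") {
    if (p == 1) return(log_c_sphere(s, n))
    if (p == 2) return(log_c_exact_p2(s, n))
    stop("exact evaluation only available for p <= 2")
  }
  lam <- s^2
  u <- ifelse(lam > 1e-10, (-n + sqrt(n^2 + 4 * lam)) / (2 * lam), 1 / n - lam / n^3)
  res <- tryCatch(
    sum(lam) / 2 + spa_piece(u, lam, n, order2) -
      spa_piece(rep(1 / n, p), rep(0, p), n, order2),
    error = function(e) stop("saddle-point evaluation failed for s = (",
                             paste(signif(s, 4), collapse = ", "),
                             "), n = ", n, ": ", conditionMessage(e)))
  res
}

#' Maximum-likelihood estimation of a vMF parameter from a sample mean
#'
#' Given the arithmetic mean `Xbar` of manifold points, computes the MLE
#' `F = M diag(s)` where `M = U V'` from the thin SVD of `Xbar` and `s`
#' maximizes `tr(diag(s) M'Xbar) - log C_{n,p}(s)` (the orthogonal-column
#' constraint of the network model). With `orthogonal_columns = FALSE` the
#' unconstrained form `F = U diag(s) V'` is used instead, in which case the
#' linear coefficients are the singular values of `Xbar`.
#'
#' @param Xbar n x p arithmetic mean of Stiefel points, full column rank.
#' @param orthogonal_columns constrain `F` to orthogonal columns (the model's
#'   case). Default `TRUE`.
#' @param method normalizer method passed to [vmf_lognorm()].
#' @param s0 optional warm start for the concentration optimizer (used by the
#'   SAEM loop, where consecutive M-steps change little).
#' @return list with components `F`, `mode`, `concentrations`, and
#'   `optim_convergence`.
#' @export
vmf_mle <- function(Xbar, orthogonal_columns = TRUE,
                    method = c("saddlepoint", "exact"), s0 = NULL) {
  method <- match.arg(method)
  Xbar <- as.matrix(Xbar)
  n <- nrow(Xbar); p <- ncol(Xbar)
  sv <- svd(Xbar)
  if (min(sv$d) < 1e-10) stop("rank-deficient sample mean; vMF MLE undefined")
  M <- sv$u %*% t(sv$v)
  coefs <- if (orthogonal_columns) diag(crossprod(M, Xbar)) else sv$d
  s0_given <- s0
  if (is.null(s0)) {
    d0 <- pmin(sv$d, 1 - 1e-10)
    s0 <- pmin(pmax(n * d0 / (1 - d0^2), 1e-3), 1e4)
  }
  nll <- function(s) vmf_lognorm(s, n, method) - sum(s * coefs)
  opt <- optim(s0, nll, method = "L-BFGS-B", lower = 0, upper = 1e6,
               control = list(maxit = if (is.null(s0_given)) 500 else 5))
  # convergence code 1 (iteration cap) is acceptable on warm-started calls:
  # SAEM only needs a generalized (improving) M-step
  if (!(opt$convergence %in% c(0, 1, 52))) {
    stop("vMF concentration optimizer did not converge (code ", opt$convergence,
         "); last iterate: ", paste(signif(opt$par, 5), collapse = ", "))
  }
  s_hat <- opt$par
  F_hat <- if (orthogonal_columns) M %*% diag(s_hat, p) else
    sv$u %*% diag(s_hat, p) %*% t(sv$v)
  list(F = F_hat, mode = M, concentrations = s_hat,
       optim_convergence = opt$convergence)
}

#' Sample from a matrix vMF distribution
#'
#' Adaptive Metropolis-Hastings chain with the projected Gaussian random-walk
#' proposal; the log of the step size is adapted toward a target acceptance
#' rate during burn-in.
#'
#' @param n_samples number of (post burn-in, thinned) draws.
#' @param F vMF parameter matrix.
#' @param burnin burn-in sweeps (default 500).
#' @param thin keep one draw in `thin` (default 5).
#' @param target_accept target acceptance rate for adaptation (default 0.3).
#' @param init initial point; defaults to the mode.
#' @return list of `n_samples` Stiefel matrices.
#' @export
rvmf <- function(n_samples, F, burnin = 500, thin = 5, target_accept = 0.3,
                 init = NULL) {
  X <- if (is.null(init)) {
    if (max(abs(F)) == 0) rstiefel_uniform(nrow(F), ncol(F)) else project_stiefel(F)
  } else init
  log_step <- log(0.3)
  acc <- 0L; t_adapt <- 0L
  out <- vector("list", n_samples)
  total <- burnin + n_samples * thin
  kept <- 0L
  ll <- sum(F * X)
  for (it in seq_len(total)) {
    Xp <- cpp_propose_stiefel(X, exp(log_step))
    llp <- sum(F * Xp)
    if (log(runif(1)) < llp - ll) { X <- Xp; ll <- llp; acc <- acc + 1L }
    if (it <= burnin && it %% 20 == 0) {
      t_adapt <- t_adapt + 1L
      g <- 1 / (2 * t_adapt^0.6)
      log_step <- log_step + if (acc / 20 > target_accept) g else -g
      acc <- 0L
    }
    if (it > burnin && (it - burnin) %% thin == 0) {
      kept <- kept + 1L
      out[[kept]] <- X
    }
  }
  out
}
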