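// Core numerical kernels: Stiefel projection, Metropolis-within-Gibbs sweeps
// over the latent (X, lambda), and the Gibbs chain for missing-edge posterior
// sampling. All randomness goes through R's RNG so set.seed() governs
// everything, including these loops.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Thin-SVD projection onto the Stiefel manifold V(n,p): M = U D V' -> U V'.
// Unique iff M has full column rank (Lemma: minimizes Frobenius distance).
static arma::mat project_stiefel_arma(const arma::mat& M, double rank_tol = 1e-12) {
  arma::mat U, V;
  arma::vec d;
  bool ok = arma::svd_econ(U, d, V, M);
  if (!ok) stop("SVD failed in Stiefel projection");
  if (d.min() <= rank_tol)
    stop("Stiefel projection undefined: input is numerically rank-deficient (min singular value %g)",
         d.min());
  return U * V.t();
}

// [[Rcpp::export]]
arma::mat cpp_project_stiefel(const arma::mat& M) {
  return project_stiefel_arma(M);
}

// Gaussian random-walk proposal projected back onto the manifold.
static arma::mat propose_stiefel(const arma::mat& X, double step) {
  const int n = X.n_rows, p = X.n_cols;
  for (int attempt = 0; attempt < 20; ++attempt) {
    arma::mat Z(n, p);
    for (int j = 0; j < p; ++j)
      for (int i = 0; i < n; ++i) Z(i, j) = R::norm_rand();
    arma::mat Y = X + step * Z;
    arma::mat U, V;
    arma::vec d;
    if (arma::svd_econ(U, d, V, Y) && d.min() > 1e-12) return U * V.t();
  }
  stop("Stiefel proposal failed repeatedly (degenerate perturbations)");
}

// [[Rcpp::export]]
arma::mat cpp_propose_stiefel(const arma::mat& X, double step) {
  if (step == 0.0) return X;
  return propose_stiefel(X, step);
}

// Masked squared Frobenius norm of (A - X diag(lam) X').
static double resid_quad(const arma::mat& A, const arma::mat& X, const arma::vec& lam,
                         const arma::mat& mask, bool use_mask) {
  arma::mat R = A - X * arma::diagmat(lam) * X.t();
  if (use_mask) R %= mask;
  return arma::dot(R, R);
}

// [[Rcpp::export]]
double cpp_resid_quad(const arma::mat& A, const arma::mat& X, const arma::vec& lam,
                      const arma::mat& mask) {
  bool use_mask = mask.n_elem > 1;
  return resid_quad(A, X, lam, mask, use_mask);
}

// Complete-data log-likelihood terms for every subject, WITHOUT the
// -log C_{n,p}(F) constant (added at the R level where the saddle-point
// normalizer lives). Returns a vector of per-subject values.
// [[Rcpp::export]]
arma::vec cpp_loglik_vec(const arma::cube& A, const arma::cube& X, const arma::mat& lam,
                         const arma::mat& F, const arma::vec& mu, double sigma_lambda,
                         double sigma_eps, const arma::mat& mask, double n_obs) {
  const int N = A.n_slices, p = lam.n_rows;
  bool use_mask = mask.n_elem > 1;
  arma::vec out(N);
  const double log2pi = std::log(2.0 * M_PI);
  for (int k = 0; k < N; ++k) {
    double q = resid_quad(A.slice(k), X.slice(k), lam.col(k), mask, use_mask);
    double obs = -q / (2.0 * sigma_eps * sigma_eps) -
                 n_obs * (std::log(sigma_eps) + 0.5 * log2pi);
    double vmf = arma::dot(F, X.slice(k));
    arma::vec dl = lam.col(k) - mu;
    double pri = -arma::dot(dl, dl) / (2.0 * sigma_lambda * sigma_lambda) -
                 p * (std::log(sigma_lambda) + 0.5 * log2pi);
    out(k) = obs + vmf + pri;
  }
  return out;
}

// One Metropolis-within-Gibbs sweep pass over all subjects: for each subject,
// n_steps alternating updates of X (projected Gaussian walk, treated as a
// symmetric kernel) and lambda (Gaussian walk). Component membership z picks
// the parameter set in the mixture case; pass K = 1 slices and z = 0 for the
// plain model. Acceptance counts are returned for step-size adaptation.
// [[Rcpp::export]]
List cpp_gibbs_sweep(const arma::cube& A, arma::cube X, arma::mat lam,
                     const arma::cube& F, const arma::mat& mu,
                     const arma::vec& sigma_lambda, const arma::vec& sigma_eps,
                     const arma::uvec& z, const arma::mat& mask,
                     int n_steps, double step_X, double step_lam,
                     bool discrete_moves) {
  const int N = A.n_slices, p = lam.n_rows;
  bool use_mask = mask.n_elem > 1;
  long acc_X = 0, acc_lam = 0;
  const long tot = (long)N * n_steps;
  for (int k = 0; k < N; ++k) {
    const unsigned c = z(k);
    const arma::mat& Fc = F.slice(c);
    const double se2 = 2.0 * sigma_eps(c) * sigma_eps(c);
    const double sl2 = 2.0 * sigma_lambda(c) * sigma_lambda(c);
    arma::mat Xk = X.slice(k);
    arma::vec lk = lam.col(k);
    double q = resid_quad(A.slice(k), Xk, lk, mask, use_mask);
    double vmf = arma::dot(Fc, Xk);
    for (int s = 0; s < n_steps; ++s) {
      // X move
      if (step_X > 0.0) {
        arma::mat Xp = propose_stiefel(Xk, step_X);
        double qp = resid_quad(A.slice(k), Xp, lk, mask, use_mask);
        double vp = arma::dot(Fc, Xp);
        double dl = -(qp - q) / se2 + (vp - vmf);
        if (std::isfinite(dl) && std::log(R::unif_rand()) < dl) {
          Xk = Xp; q = qp; vmf = vp; ++acc_X;
        }
      } else ++acc_X;
      // lambda move
      if (step_lam > 0.0) {
        arma::vec lp = lk;
        for (int j = 0; j < p; ++j) lp(j) += step_lam * R::norm_rand();
        double qp = resid_quad(A.slice(k), Xk, lp, mask, use_mask);
        arma::vec d1 = lp - mu.col(c), d0 = lk - mu.col(c);
        double dl = -(qp - q) / se2 - (arma::dot(d1, d1) - arma::dot(d0, d0)) / sl2;
        if (std::isfinite(dl) && std::log(R::unif_rand()) < dl) {
          lk = lp; q = qp; ++acc_lam;
        }
      } else ++acc_lam;
      // discrete mode-jumping moves: a column transposition (applied to X
      // and lambda alike) leaves the reconstruction X diag(lam) X' and the
      // observation term invariant, so the MH ratio involves only the vMF
      // and weight-prior terms; likewise a column sign flip touches only
      // the vMF term. These symmetric proposals let the chain cross the
      // permutation/sign modes that small random-walk steps cannot.
      if (discrete_moves && step_X > 0.0 && p > 1) {
        int i = (int)(R::unif_rand() * p), j = (int)(R::unif_rand() * p);
        if (i != j && i < p && j < p) {
          const arma::vec& mc = mu.col(c);
          double dvmf = arma::dot(Fc.col(i), Xk.col(j)) +
                        arma::dot(Fc.col(j), Xk.col(i)) -
                        arma::dot(Fc.col(i), Xk.col(i)) -
                        arma::dot(Fc.col(j), Xk.col(j));
          double dpri = (-(lk(j) - mc(i)) * (lk(j) - mc(i)) -
                          (lk(i) - mc(j)) * (lk(i) - mc(j)) +
                          (lk(i) - mc(i)) * (lk(i) - mc(i)) +
                          (lk(j) - mc(j)) * (lk(j) - mc(j))) / sl2;
          if (std::log(R::unif_rand()) < dvmf + dpri) {
            Xk.swap_cols(i, j);
            std::swap(lk(i), lk(j));
            vmf += dvmf;
          }
        }
        int f = (int)(R::unif_rand() * p);
        if (f < p) {
          double dflip = -2.0 * arma::dot(Fc.col(f), Xk.col(f));
          if (std::log(R::unif_rand()) < dflip) {
            Xk.col(f) *= -1.0;
            vmf += dflip;
          }
        }
      }
    }
    X.slice(k) = Xk;
    lam.col(k) = lk;
  }
  return List::create(_["X"] = X, _["lam"] = lam,
                      _["accept_X"] = (double)acc_X / tot,
                      _["accept_lam"] = (double)acc_lam / tot);
}

// Gibbs chain for the posterior of masked entries of a single matrix:
// p(A_miss, X, lambda | A_obs; theta). Masked entries have an exact Gaussian
// conditional N(reconstruction, sigma_eps^2); X and lambda use the same MH
// kernels as the fitting chain (against the full-matrix likelihood, current
// imputations included). miss is a 2 x m matrix of 0-based (i, j) upper pairs.
// Step sizes adapt during burn-in toward target acceptance.
// [[Rcpp::export]]
List cpp_impute_gibbs(arma::mat A, const arma::umat& miss, arma::mat X, arma::vec lam,
                      const arma::mat& F, const arma::vec& mu, double sigma_lambda,
                      double sigma_eps, int n_sweeps, int burnin,
                      double step_X, double step_lam, double target_accept,
                      bool fix_latents, int thin, int mh_per_sweep) {
  const int p = lam.n_elem;
  const int m = miss.n_cols;
  const double se2 = 2.0 * sigma_eps * sigma_eps;
  const double sl2 = 2.0 * sigma_lambda * sigma_lambda;
  const arma::mat no_mask(1, 1);
  int kept = 0;
  for (int s = burnin; s < n_sweeps; s += thin) ++kept;
  arma::mat draws(m, kept);
  arma::mat recon = X * arma::diagmat(lam) * X.t();
  int col = 0;
  double lsX = std::log(step_X), lsL = std::log(step_lam);
  int accX = 0, accL = 0, adapt_t = 0;
  for (int s = 0; s < n_sweeps; ++s) {
    // exact conditional for the masked entries
    for (int e = 0; e < m; ++e) {
      const unsigned i = miss(0, e), j = miss(1, e);
      double v = recon(i, j) + sigma_eps * R::norm_rand();
      A(i, j) = v;
      A(j, i) = v;
    }
    if (!fix_latents) {
      double q = resid_quad(A, X, lam, no_mask, false);
      double vmf = arma::dot(F, X);
      for (int rep = 0; rep < mh_per_sweep; ++rep) {
        // X move
        arma::mat Xp = propose_stiefel(X, std::exp(lsX));
        double qp = resid_quad(A, Xp, lam, no_mask, false);
        double vp = arma::dot(F, Xp);
        if (std::log(R::unif_rand()) < -(qp - q) / se2 + (vp - vmf)) {
          X = Xp; q = qp; vmf = vp; ++accX;
        }
        // lambda move
        arma::vec lp = lam;
        for (int jj = 0; jj < p; ++jj) lp(jj) += std::exp(lsL) * R::norm_rand();
        qp = resid_quad(A, X, lp, no_mask, false);
        arma::vec d1 = lp - mu, d0 = lam - mu;
        if (std::log(R::unif_rand()) <
            -(qp - q) / se2 - (arma::dot(d1, d1) - arma::dot(d0, d0)) / sl2) {
          lam = lp; q = qp; ++accL;
        }
      }
      recon = X * arma::diagmat(lam) * X.t();
      // adapt during burn-in, every 20 sweeps
      if (s < burnin && (s + 1) % 20 == 0) {
        ++adapt_t;
        double g = 1.0 / (2.0 * std::pow((double)adapt_t, 0.6));
        lsX += (accX / (20.0 * mh_per_sweep) > target_accept ? g : -g);
        lsL += (accL / (20.0 * mh_per_sweep) > target_accept ? g : -g);
        accX = 0; accL = 0;
      }
    }
    if (s >= burnin && (s - burnin) % thin == 0) {
      for (int e = 0; e < m; ++e) draws(e, col) = A(miss(0, e), miss(1, e));
      ++col;
    }
  }
  return List::create(_["draws"] = draws, _["X"] = X, _["lam"] = lam);
}

// Haar-uniform draw on V(n,p): QR of a Gaussian matrix with the sign of the
// R diagonal fixed, vectorized over many draws for Monte-Carlo work.
// [[Rcpp::export]]
arma::cube cpp_rstiefel(int n, int p, int m) {
  arma::cube out(n, p, m);
  for (int k = 0; k < m; ++k) {
    arma::mat Z(n, p);
    for (int j = 0; j < p; ++j)
      for (int i = 0; i < n; ++i) Z(i, j) = R::norm_rand();
    arma::mat Q, R;
    if (!arma::qr_econ(Q, R, Z)) stop("QR failed");
    for (int j = 0; j < p; ++j)
      if (R(j, j) < 0) Q.col(j) *= -1.0;
    out.slice(k) = Q;
  }
  return out;
}

// Mean Frobenius distance between independent Haar-uniform pairs.
// [[Rcpp::export]]
List cpp_uniform_pair_distance(int n, int p, int m) {
  double s = 0.0, s2 = 0.0;
  for (int k = 0; k < m; ++k) {
    arma::cube XY = cpp_rstiefel(n, p, 2);
    double d = arma::norm(XY.slice(0) - XY.slice(1), "fro");
    s += d; s2 += d * d;
  }
  double mean = s / m;
  double sd = std::sqrt(std::max(0.0, s2 / m - mean * mean));
  return List::create(_["mean"] = mean, _["sd"] = sd);
}

// Monte-Carlo estimate of log E_haar[exp(tr(F'X))] with standard error of the
// log-mean; used as an independent integration oracle for the saddle-point
// normalizer.
// [[Rcpp::export]]
List cpp_vmf_mc_lognorm(const arma::mat& F, int m) {
  const int n = F.n_rows, p = F.n_cols;
  double s = 0.0, s2 = 0.0;
  for (int k = 0; k < m; ++k) {
    arma::cube Xc = cpp_rstiefel(n, p, 1);
    double v = std::exp(arma::dot(F, Xc.slice(0)));
    s += v; s2 += v * v;
  }
  double mean = s / m;
  double var = std::max(0.0, s2 / m - mean * mean);
  double se_log = std::sqrt(var / m) / mean;
  return List::create(_["log_mean"] = std::log(mean), _["se"] = se_log);
}
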