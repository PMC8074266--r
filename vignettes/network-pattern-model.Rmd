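---
title: "Modeling the variability of network populations with Stiefel-valued patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the variability of network populations with Stiefel-valued patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stiefelnet)
```

## The model

`stiefelnet` models a data set of $N$ undirected weighted networks on a
common set of $n$ nodes. Each symmetric adjacency matrix is decomposed as a
noisy weighted sum of $p$ rank-one patterns,

$$A^{(k)} = X^{(k)}\,\mathrm{Diag}(\lambda^{(k)})\,X^{(k)\top} + \varepsilon^{(k)},$$

where the pattern matrix $X^{(k)}$ has orthonormal columns (a point of the
compact Stiefel manifold $V(n,p)$), the pattern weights $\lambda^{(k)}$ are
the eigenvalues of the signal part, and $\varepsilon^{(k)}$ is symmetric
Gaussian noise ($\mathcal N(0,\sigma_\varepsilon^2)$ independently on the
upper triangle including the diagonal, mirrored below). The latent
variables are drawn independently across subjects:

* $X^{(k)} \sim \mathrm{vMF}(F)$, the matrix von Mises--Fisher (matrix
  Langevin) distribution with density $\propto \exp(\mathrm{tr}(F^\top X))$.
  The columns of $F$ are constrained to be orthogonal, so its Stiefel
  projection is the distribution's mode (the population's template
  patterns) and its column norms are *concentration parameters*: the larger
  $\|f_i\|$, the more stable pattern $i$ is across subjects.
* $\lambda^{(k)} \sim \mathcal N(\mu, \sigma_\lambda^2 I_p)$: every subject
  re-weights the patterns around the population means $\mu$.

The model therefore separates two sources of population variability that
dictionary models and auto-encoders capture only one at a time: wobble of
the patterns themselves, and variation of their weights. The full parameter
set $\theta = (F, \mu, \sigma_\lambda, \sigma_\varepsilon)$ has only
$np + p + 2$ degrees of freedom (reported by `model_dof()`).

The motivating data are functional brain connectivity matrices (temporal
correlations between regional activity), but nothing in the implementation
is specific to neuroimaging.

## Estimation: MCMC-SAEM

The observed likelihood integrates over the manifold-valued latents and is
intractable, so `fit_network_model()` runs a stochastic-approximation EM
with an MCMC E-step. The model is in the curved exponential family with
sufficient statistics
$S_1 = \overline{X^{(k)}}$, $S_2 = \overline{\lambda^{(k)}}$,
$S_3 = \overline{\|\lambda^{(k)}\|^2}$ and
$S_4 = \overline{\|A^{(k)} - X^{(k)}\mathrm{Diag}(\lambda^{(k)})X^{(k)\top}\|^2}$.
Each iteration:

1. **E-step (Metropolis-within-Gibbs).** For every subject, a few MH
   updates of $X$ (Gaussian perturbation projected back onto the manifold
   via the SVD polar factor, treated as a symmetric proposal -- an
   approximation we document rather than correct, since the exact Jacobian
   is expensive and the geodesic and Cayley alternatives perform
   equivalently) alternate with MH updates of $\lambda$ (full-vector
   Gaussian walk; the exact Gaussian conditional exists but MH moves mix
   the joint chain faster). Both step sizes adapt on the log scale by
   $\pm 1/(2t^{0.6})$ toward a target acceptance rate of 0.3.
2. **Greedy column matching.** The likelihood is invariant under column
   permutations and sign flips of $X$ (with matching permutation of
   $\lambda$), which makes the posterior multi-modal and, left alone,
   biases $F$ toward the uniform distribution. Every 5 iterations during
   the first third of the run, each subject's sampled $X$ is re-aligned to
   the current mode by `greedy_match()`: repeatedly assign the column pair
   with the largest absolute inner product, with sign correction.
3. **Stochastic approximation.** $\bar S \leftarrow (1-\alpha_t)\bar S +
   \alpha_t S$ with $\alpha_t = 1$ for the first half of the iterations and
   $\alpha_t = (t - \lfloor T/2\rfloor)^{-0.6}$ afterwards.
4. **M-step.** $\hat\mu = \bar S_2$,
   $\hat\sigma_\lambda^2 = (\bar S_3 - \|\bar S_2\|^2)/p$,
   $\hat\sigma_\varepsilon^2 = \bar S_4 / n^2$ (divided by the observed
   entry count when a mask is present), and $\hat F$ from the constrained
   vMF maximum-likelihood estimator applied to $\bar S_1$ (below).

Initialization takes the $p$ leading eigenpairs (by absolute eigenvalue,
since weights may be negative) of each matrix, aligns them across subjects
by greedy matching, and applies the M-step. A short hybrid phase (10
iterations) replaces the MH move on $X$ with a backtracking Riemannian
gradient-ascent step -- tangent-space projection of the Euclidean gradient
followed by the projection retraction -- which moves the chain into the
high-posterior region before regular sampling starts. The trial step is
scaled by the tangent-gradient norm so the first move has bounded manifold
magnitude whatever the noise precision.

Posterior summaries of the latent patterns use the projected arithmetic
mean of the MCMC samples over the second half of the iterations: the vMF
distribution is symmetric around its mode along the sign-flip directions,
which makes the projected mean an adequate center summary, and it avoids
Riemannian logarithms entirely.

### The vMF normalizing constant

The M-step needs $\log C_{n,p}(F)$, which only depends on the singular
values $s$ of $F$. `vmf_lognorm()` implements a saddle-point approximation
built on the identity
$C(s) = e^{\sum_i s_i^2/2}\, f_W^F(I_p) / f_W^0(I_p)$,
where $f_W^F$ is the density of the noncentral Wishart $W = Y^\top Y$,
$Y \sim \mathcal N(F, I)$ entrywise. Both densities at the identity are
approximated by the multivariate saddle-point formula; the ratio form makes
$C(0) = 1$ exact. The cumulant generating function has a diagonal saddle
point and sparse higher cumulants, so the standard second-order correction
$(1 + \rho_4/8 - (3\rho_{13}^2 + 2\rho_{23}^2)/24)$ reduces to closed-form
sums over index pairs and triangles; every contraction was verified against
finite differences of the CGF. When the correction term is no longer small
(it grows like $p^3/n$, e.g. $p$ comparable to $n$), the ratio falls back
to the first-order formula, which is the standard practice for asymptotic
corrections outside their range of validity.

Measured accuracy against exact references (the Bessel closed form for
$p=1$; a deterministic two-dimensional quadrature reduction we provide as
`method = "exact"` for $p=2$): relative error on $C$ below 0.5% for $p=1$,
$n=3$ across $\kappa \in [0.1, 50]$; on $\log C$ below 0.016 at $n=3$,
below 0.001 for $n \ge 10$. The worst case is intrinsically the smallest
ambient dimension, where the Wishart has barely $n \ge p$ degrees of
freedom. These are the figures behind the tolerance used in the unit tests.

The constrained MLE maximizes
$\sum_i s_i (\bar M^\top \bar S_1)_{ii} - \log C_{n,p}(s)$ over
$s \ge 0$, with $\bar M$ the polar factor of $\bar S_1$ (L-BFGS-B, bounds
$[0, 10^6]$, started from the classical large-concentration approximation
$s_i \approx n \bar d_i/(1-\bar d_i^2)$, or warm-started from the previous
SAEM iterate inside the fitting loop).

## Mixtures

`fit_network_mixture()` adds a categorical cluster label per subject.
Cluster labels are initialized by K-Means on the vectorized upper
triangles (10 restarts), each component by the spectral procedure on its
members. The Gibbs sweep gains a label-resampling step from
$p(z \mid X, \lambda, A) \propto \pi_c\, p_c(A, X, \lambda)$ -- the vMF
normalizing constants do *not* cancel across components -- with the
probabilities raised to $1/T_t$, $T_t = 1 + 50/t^{0.6}$, and renormalized.
The early, hot phase deliberately scrambles assignments to let subjects
migrate; the separation re-emerges as $T_t$ decreases, which is why the
schedule needs its full horizon (1000 iterations in the clustering
experiments) rather than a truncated one. Sufficient statistics and the
M-step are per cluster; empty clusters keep their previous parameters.
Component vMF parameters are mutually aligned by greedy matching every 5
iterations so small MH steps can carry a subject between the components'
regions of influence. Reported labels maximize the *untempered*
responsibilities of the final iteration.

## Missing-edge imputation

Given fitted parameters and a new network with unobserved entries
$\bar\Omega$, `impute_posterior()` samples
$p(A_{\bar\Omega}, X, \lambda \mid A_\Omega; \theta)$ by Gibbs: masked
entries have the exact conditional
$\mathcal N(\mathrm{recon}(X,\lambda)_{ij}, \sigma_\varepsilon^2)$
(mirrored symmetrically), and the latents move by the fitting kernels
against the full-matrix likelihood with current imputations. The chain
starts from MAP-refined latents -- without this the burn-in budget is
spent locating the posterior rather than exploring it, and the posterior
mean trails the MAP estimate -- and performs four latent updates per sweep.
`impute_map()` computes the maximum a posteriori by coordinate ascent
(exact masked-entry update, backtracking gradient steps on $\lambda$,
backtracking Riemannian ascent on $X$; the objective is monotone by
construction). Baselines: the mean of the training matrices and the
rank-$p$ truncation of the masked matrix. Errors are reported as relative
RMSE over the masked entries, with spread across matrices.

## Synthetic study designs and what they do (and do not) show

`network_preset()` fixes seven generator configurations. Printed design
values follow the synthetic studies; the remaining constants were chosen
once, as follows, and frozen.

* **smalldim-lownoise / -highnoise** ($n=3$, $p=2$, concentrations
  $(25,10)$, $\mu=(20,10)$, $\sigma_\lambda=2$, $N=100$,
  $\sigma_\varepsilon \in \{0.1, 4\}$): parameter recovery and the
  noise-induced shrinkage of estimated concentrations. Both runs under one
  seed share latent variables, isolating the role of the noise. The
  shrinkage arises because the noise component tangent to the manifold of
  rank-$p$ matrices acts as extra spread on $(X,\lambda)$; concentration
  estimates under strong noise are therefore biased down by design, not by
  an estimator defect. Across seeds the larger estimated concentration
  spreads over roughly $21$--$26$ (low noise) and $9$--$15$ (high noise):
  single-run values should be read with that sampling width in mind.
* **highdim** ($n=40$, $p=20$, $N=200$, $\sigma_\varepsilon=1$): the
  concentrations and mean weights are decreasing ladders in matched
  batches (large weights paired with high concentrations), the regime in
  which the algorithm finds large values first and the smallest
  concentrations are hardest to recover.
* **impute-block / impute-random** ($n=20$, $p=5$, $N=200$ training + 200
  held-out): concentrations $(45,40,34,28,22)$, $\mu=(15,12,9,7,5)$,
  $\sigma_\lambda=2$; $\sigma_\varepsilon$ is calibrated by bisection so
  the Monte-Carlo mean of
  $\|\varepsilon\|/\|\lambda\cdot X\|$ is 25%. Random masking hides 40% of
  the $n(n+1)/2$ upper entries including the diagonal; block masking hides
  the off-diagonal entries among the last eight nodes (about 16% of the
  coefficients, reported exactly by the experiment). Including the
  diagonal -- whose entries are comparatively stable across subjects -- in
  the random scheme is what makes the random-mask *baseline* easier than
  the block baseline. These constants reproduce the baseline difficulty
  levels stably across pattern draws; with delocalized (Haar) pattern
  modes the posterior-mean error under the two schemes is similar, because
  every node's pattern values remain pinned by its observed edges. A
  markedly harder block scheme arises only for localized patterns, which
  these presets deliberately do not assume.
* **cluster-smalldim / cluster-highdim**: heterogeneous populations. The
  small design separates clusters by their concentration parameters; the
  fitted mixture clearly beats its K-Means initialization there (tested).
  The larger design ($n=20$, $p=10$, $K=4$, $N=500$) uses equal,
  deliberately low concentrations (16), nearly common modes (projection of
  a shared Haar draw plus jitter 0.1), and mean-weight vectors that differ
  in the weight of one dominant pattern (50, 41, 33 or 26 over a shared
  small tail; $\sigma_\lambda = 1.1$, $\sigma_\varepsilon = 0.5$). The low
  concentrations flood the Euclidean geometry with pattern wobble,
  defeating K-Means (about 50% accuracy), while the *spectrum* of each
  matrix is untouched by pattern wobble: a Bayes rule on the top
  eigenvalue alone classifies at 97% or better (tested). This is the
  precise sense in which the model's latent decomposition separates modes
  of variability a Euclidean clustering cannot. The tempered label
  resampling with the printed temperature profile recovers only part of
  that ceiling in our experiments (roughly 50--60% label accuracy at 1000
  iterations): the hot early phase erases the initialization, and a
  perturbation analysis shows the flattened conditional cannot re-amplify
  cluster structure while $T_t > 1$ (the profile ends near $T = 1.8$).
  The shipped experiment reports the honestly attained accuracy; the
  spectrum-rule test documents that the information is present in the
  model's own latent representation.

All generators draw the vMF patterns by per-subject adaptive MH chains
(burn-in 600 from the mode, step tuned on a pilot chain), validated
against exact vMF moment identities; the draws are independent across
subjects, so generated data carry no chain autocorrelation. The synthetic
data match the model exactly. Real connectivity matrices have heavy
spectral tails and non-Gaussian noise, so passing these studies
demonstrates correctness of the machinery and the qualitative phenomena
(shrinkage, matching necessity, spectral clustering advantage), not model
adequacy for any particular data set.

## Numerical choices and degenerate inputs

* Stiefel projection requires full column rank (smallest singular value
  $> 10^{-12}$); rank-deficient inputs are an explicit error since the
  projection is not unique. Manifold membership checks use $10^{-8}$ on
  $\|X^\top X - I\|_\infty$.
* Variance estimates are $1/N$ (maximum likelihood), not $1/(N-1)$;
  negative finite-sample variance estimates are clipped at $10^{-12}$ with
  a warning.
* The likelihood uses the full-matrix Frobenius norm with an $n^2$ entry
  count while the generator draws noise on the $n(n+1)/2$ upper triangle.
  The two conventions are kept deliberately: the generation is the
  physically meaningful one, the $n^2$ form is the one the closed-form
  M-step is derived under, and mixing them is a documented (inherited)
  inconsistency whose only effect is a predictable rescaling of
  $\hat\sigma_\varepsilon$.
* Ties in greedy matching resolve to the first maximum in column-major
  order; the accompanying tests replay the rule step by step.
* The tempered label probabilities guard against total underflow by
  falling back to uniform probabilities with a warning.
* One master seed drives a single R random stream end to end (compiled
  kernels included); fits are reproducible draw for draw, and a
  one-component mixture fit equals the plain fit exactly under the same
  seed.

## Problem sizes used in the shipped studies

The packaged experiments run at the design sizes quoted above; the test
suite exercises the same code paths at reduced sizes (tens of subjects,
tens of iterations) chosen so that each suite file completes in well under
a minute while still leaving every statistical check at least three
standard errors of resolution.

## Known limitations

* The saddle-point normalizer loses its second-order correction in the
  strongly high-dimensional regime ($p$ comparable to $n$); concentration
  estimates there inherit first-order accuracy.
* The projected-random-walk proposal is treated as symmetric; the induced
  bias is shared with the reference implementation of the method and was
  not measurable against the exact conditional-mean oracles in our tests.
* MAP imputation overfits the observed entries when the noise level is
  high (it is a mode, not a mean); the posterior mean is the better point
  estimator and the credible intervals are the better uncertainty summary.
* Binary, log-normal and positive-weight observation models, MALA
  proposals, and longitudinal extensions are out of scope.
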