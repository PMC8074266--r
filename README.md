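# stiefelnet

Statistical modeling of the variability in data sets of undirected weighted
networks that share a node set — the typical situation in population
neuroimaging, where every subject contributes a functional connectivity
matrix over the same brain parcellation, and more generally wherever many
networks are measured over common units (gene interaction panels, repeated
observations of one evolving network, ...).

## The model

Each symmetric adjacency matrix is decomposed as a noisy weighted sum of
rank-one orthonormal patterns:

```
A(k) = X(k) Diag(lambda(k)) X(k)' + eps(k),          k = 1..N
X(k)      ~ vMF(F)            on the Stiefel manifold V(n,p)
lambda(k) ~ N(mu, sigma_lambda^2 I_p)
eps(k)    ~ symmetric Gaussian noise, sd sigma_eps
```

The matrix von Mises–Fisher distribution `vMF(F)` (density proportional to
`exp(tr(F'X))`) describes how each subject's patterns wobble around a
population template: the projection of `F` onto the manifold is the mode,
and the column norms of `F` are concentration parameters measuring how
stable each pattern is across subjects. The weights `lambda(k)` are the
eigenvalues of the signal part. The model captures both sources of
population variability — pattern wobble and weight variation — with only
`n*p + p + 2` parameters.

Estimation is maximum likelihood by MCMC-SAEM: a Metropolis-within-Gibbs
E-step on the manifold-valued latents (with greedy column matching against
permutation/sign non-identifiability), Robbins–Monro averaging of the
sufficient statistics, and a closed-form M-step whose only numerical
ingredient is a saddle-point approximation of the vMF normalizing
constant. The package also provides a tempered mixture extension for
heterogeneous populations and posterior imputation of missing edge weights
with credible intervals.

## Worked example

Simulate a small population (3 nodes, 2 patterns with concentrations
(25, 10), mean weights (20, 10), weight spread 2, noise 0.1) and refit it:

```r
library(stiefelnet)
set.seed(42)
truth <- model_params(sweep(rstiefel_uniform(3, 2), 2, c(25, 10), `*`),
                      mu = c(20, 10), sigma_lambda = 2, sigma_eps = 0.1)
sim <- sample_networks(truth, N = 100)
fit <- fit_network_model(sim$dataset, p = 2,
                         saem_config(n_iterations = 100, mcmc_steps = 20))
print(fit$params)
#> Network pattern model parameters (n = 3 , p = 2 )
#>   concentrations: 27.83 13.52
#>   mu:             19.95 9.945
#>   sigma_lambda:   1.921
#>   sigma_eps:      0.05463
#>   degrees of freedom: 10

al <- greedy_match(vmf_mode(fit$params$F), vmf_mode(truth$F))
norm(al$X - vmf_mode(truth$F), "F")
#> [1] 0.045
```

The template patterns are recovered to Frobenius distance 0.045, the mean
weights to a fraction of a percent, and the estimated concentrations
(27.8, 13.5) sit near the truth (25, 10) — concentration estimates carry a
sampling spread of a few units at `N = 100` and shrink systematically when
the observation noise grows, because noise tangent to the low-rank matrix
manifold is indistinguishable from extra pattern wobble. Running the same
example with `sigma_eps = 4` shows exactly that shrinkage.

Diagnostics (`model_diagnostics`) report per-subject relative
reconstruction errors, the proportion of variance captured by the rank-p
part, and a simulated uniform-frame concentration baseline below which an
estimated concentration carries no information. Missing-edge inference is
available through `impute_posterior` (Gibbs posterior mean + 95% credible
intervals) and `impute_map`, with `baseline_mean_impute` and
`baseline_lowrank_truncate` as references, and `fit_network_mixture`
clusters heterogeneous populations. Ready-made synthetic study designs are
exposed by `network_preset()` / `run_experiment()`, and a command-line
front end lives in `inst/cli/stiefelnet-cli.R`.

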