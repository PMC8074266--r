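Package: stiefelnet
Title: Latent Pattern Models for Populations of Weighted Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative modeling of data sets of undirected weighted networks
    sharing a common node set. Each adjacency matrix is decomposed as a noisy
    weighted sum of rank-one orthonormal patterns: the pattern matrix lives on
    the Stiefel manifold and follows a matrix von Mises-Fisher distribution,
    the pattern weights are Gaussian. Parameters are estimated by maximum
    likelihood with an MCMC-SAEM algorithm (Metropolis-within-Gibbs E-step,
    saddle-point approximation of the von Mises-Fisher normalizing constant in
    the M-step, greedy column matching against permutation and sign
    non-identifiability). The model extends to mixtures for heterogeneous
    populations with tempered cluster-label sampling, and supports posterior
    inference of missing edge weights with credible intervals.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
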