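Package: dpmmcat
Title: Dirichlet Process Mixture Clustering of Categorical Survey Responses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Bayesian nonparametric clustering of multivariate categorical
    survey responses with a Dirichlet process mixture of independent
    categorical distributions. Partitions are sampled by a collapsed Gibbs
    sampler built on the Chinese restaurant process with closed-form
    Dirichlet-categorical predictive likelihoods; a consensus (median)
    partition is found by greedy minimisation of the mean transfer distance
    to the posterior draws, solved via a linear sum assignment reduction.
    Includes per-cluster stability measures (transfer and Mirkin
    similarities), cluster-versus-outcome profiling with enrichment ratios,
    and a synthetic-data generator emulating panel-survey concern items with
    a latent cluster structure and a cluster-conditional categorical outcome.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
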