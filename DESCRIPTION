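Package: gergm
Title: Generalized Exponential Random Graph Models for Valued Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Specification, simulation and maximum likelihood estimation of
    generalized exponential random graph models (GERGMs) for directed
    networks whose edges carry continuous values.  Network dependence
    (reciprocity, transitivity, cycling, degree heterogeneity) is modelled
    by an exponential family on a latent network with edges restricted to
    the unit interval, composed with parameterized monotone marginal
    transformations (Gaussian, Cauchy, or bounded-interval) onto the
    observed edge support.  Includes exact Gibbs sampling from the
    restricted-network distribution via truncated-exponential full
    conditionals, maximum pseudolikelihood starting values, alternating
    MLE / Monte Carlo MLE estimation with importance-sampled
    normalizing-constant ratios, Wald and likelihood-ratio block tests,
    MCMC convergence and degeneracy diagnostics (Geweke, Gelman-Rubin,
    mean-edge trace), and simulation-based goodness of fit for the
    dependence structure.
License: MIT
Encoding: UTF-8
Imports: Rcpp, stats, utils, jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
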