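Package: parMCMCgp
Title: Parallel Bayesian Computation for Whole-Genome Prediction
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Building blocks for high-performance Bayesian computation in
    animal breeding and genetics: closed-form conjugate normal posteriors
    used as exact oracles, a reproducible master/worker parallel Monte Carlo
    and multi-chain MCMC engine with counter-style random-number substreams,
    Gibbs samplers for BayesC-pi, BayesC with fixed pi and the Bayesian
    LASSO, Gelman-Rubin convergence diagnostics with burn-in-aware speedup
    laws, and the BayesCpC feature-selection plus cross-validation pipeline
    for SNP-panel optimisation, together with seeded synthetic-data
    generators for genotypes, phenotypes and group-means fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, parallel, Rcpp, yaml, optparse
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), coda, statmod, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
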