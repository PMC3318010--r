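Package: driftshift
Title: Trait-Dependent Diversification and Directional Trends in Body Size on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test for directional macroevolutionary trends (Cope's rule
    versus miniaturization) in a continuous character on time-calibrated
    phylogenies. Implements Pagel's lambda phylogenetic-signal estimation under
    generalized least squares with maximum-likelihood and MCMC (harmonic-mean and
    stepping-stone marginal likelihood) modes; a quantitative-trait
    state-dependent speciation/extinction (QuaSSE-style) likelihood engine with
    drift-diffusion character evolution and constant, linear, sigmoidal and
    hump-shaped speciation functions; model selection by AIC, nested chi-square
    tests and Bayes factors, both on single trees and aggregated over Bayesian
    posterior tree samples; substitution-saturation and node-density artifact
    diagnostics; and forward birth-death simulators for trees, traits and DNA
    alignments used to validate every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    nloptr,
    optparse,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
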