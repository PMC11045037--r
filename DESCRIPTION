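Package: capbandit
Title: Capacity-Limited Bayesian Decision-Making for Multi-Armed Bandits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation tools for Bayesian bandit agents that operate under
    information-processing constraints. Provides conjugate per-arm posteriors
    (Beta-Bernoulli and Gaussian), exact information-theoretic quantities on
    discrete belief sources and action channels, a Blahut-Arimoto solver for
    the rate-distortion problem over Monte-Carlo-discretized beliefs, the
    Thompson-Sampling family of decision rules (Thompson Sampling, satisficing
    Thompson Sampling, and rate-distortion Thompson Sampling realized via
    Blahut-Arimoto, alongside Boltzmann and uniform baselines), and an
    experiment harness for regret curves, per-period rate diagnostics,
    rate-distortion trade-off tables, and information-cost sweeps of action
    distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
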