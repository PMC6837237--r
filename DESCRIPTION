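Package: hemodetect
Title: Bayesian Localization of Arterial Wall Defects from Pulse-Wave
    Velocity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates nonlinear one-dimensional pulse-wave propagation in
    branching arterial networks with a discontinuous Galerkin solver,
    generates noisy synthetic velocity observations, and localizes
    structural defects (aneurysms and stenoses) by Bayesian model
    selection. Posterior samples and model evidence are computed with a
    transitional Markov chain Monte Carlo (TMCMC) sampler; candidate
    defect models are ranked by their posterior probability given
    velocity measurements at a small number of sensors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    parallel,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
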