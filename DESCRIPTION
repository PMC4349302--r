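Package: certkinetics
Title: Bayesian Kinetic Modeling of PKD-PI4KIIIbeta-CERT Signaling at the
    Trans-Golgi Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary-differential-equation models of the PKD, PI4KIIIbeta and
    CERT phosphorylation network that controls ceramide transfer from the ER
    to the trans-Golgi network, in two competing variants (shuttle with
    positive feedback, neck-swinging with negative feedback). Provides
    perturbation-protocol simulation, Gaussian likelihoods with profiled
    blot-gain nuisances, log-uniform priors, parallel-tempering MCMC,
    marginal likelihoods by thermodynamic integration with Bayes-factor
    ranking, posterior predictions of endogenous steady states, fluxes and
    regulation operating points, perturbation-response analyses, absolute
    protein quantification by inverse regression from standard curves, and a
    synthetic-data generator emulating the calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
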