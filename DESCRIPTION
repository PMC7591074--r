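Package: intentgame
Title: Bayesian Modelling of Intent Attribution in Serial Dictator Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a grid-based Bayesian observer model of harmful-intent and
    self-interest attributions made by participants playing repeated dictator
    games against a sequence of partners. Beliefs over a 9x9 lattice of partner
    attributes are updated trial by trial from observed returns through a
    sharpened-binomial policy map, with a learning rate carrying beliefs across
    partners. Provides per-participant MAP estimation of the six latent
    parameters (prior modes and uncertainties for both attributions, policy
    uncertainty, and cross-partner learning rate) by grid search plus local
    ascent, forward simulation of sessions and populations, synthetic-population
    generation with paranoia (GPTS) couplings, fit diagnostics against the
    chance log-likelihood floor, parameter-recovery studies, and a
    partial-correlation network of fitted parameters with paranoia-moderated
    edges.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
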