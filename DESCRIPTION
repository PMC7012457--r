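Package: collareffects
Title: Quantifying Short-Term GPS-Collar Effects on Tagged Ungulates
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify short-term effects of GPS-collar fitting on a
    tagged ungulate from three independent data streams: ethogram tallies
    from scan sampling (Bayesian multinomial logistic regression with
    individual random effects and a credible-interval significance rule),
    fecal glucocorticoid metabolite (FGM) concentrations (piecewise
    regression model competition with an estimated recovery breakpoint,
    selected by leave-one-out cross-validation), and collar accelerometer
    data (feature extraction, random-forest behavior classification, and
    binomial time-series models of post-collaring headshaking with
    exponential-decay, day/night, and harmonic-mixture structure). Includes
    a synthetic-data generator emulating all three data streams, a shared
    MCMC engine with convergence diagnostics, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
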