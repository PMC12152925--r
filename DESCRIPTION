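Package: rmfilter
Title: Replicator-Mutator Dynamics as Sequential Bayesian Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools connecting continuous-time, continuous-trait
    replicator-mutator (Crow-Kimura) dynamics to stochastic filtering.
    Provides finite-difference solvers for the Crow-Kimura PDE driven by
    piecewise-linear smoothed observations and for modified Zakai equations
    in Ito and Stratonovich interpretations; the linear-Gaussian (r,s)
    moment filter with its ensemble Kalman-Bucy variants and the covariance
    inflation correspondence; Fisher-Rao gradient-flow (tempering) operators
    for continuous-time Bayesian inversion; and closed-form asymptotic
    bias/variance analysis of biased linear-Gaussian filtering, including
    the optimal (r,s) design formulas that minimise asymptotic mean squared
    error while calibrating the reported covariance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
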