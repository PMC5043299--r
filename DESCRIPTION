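Package: gangdyn
Title: Eco-Epidemiological Dynamics of Police-Gang Interaction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for a modified predator-prey model of the interaction
    between police officers (predators) and gang members (prey), with
    SI-type social contagion in both populations and a cooperative
    Beddington-De Angelis functional response for arrests. Computes the
    model's equilibria (including the coexistence state via quartic
    elimination cross-checked against bracketed root finding), linear
    stability via analytic Jacobians and Routh-Hurwitz conditions,
    closed-form transcritical bifurcation thresholds with numerical scan
    refinement, and time-series simulation of the governing ODEs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
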