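Package: tkcd
Title: Toxicokinetics Cell Demography Modelling of the Gut Epithelium
Version: 0.3.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates metal (or general toxicant) kinetics in invertebrates
    with a cell-demography model of the gut epithelium: the intestine is a
    population of epithelial cells partitioned into discrete contamination
    classes with class-specific death probabilities, constant cell production,
    and per-cell toxicant absorption proportional to the instantaneous influx
    per cell. Provides the nonlinear ODE system and its numerical integration
    over piecewise-constant exposure schedules, stationary-state solvers based
    on the inter-class proportionality relations, derived observables (body
    burden, percentage cell loss, the state-dependent instantaneous
    elimination rate), dose-to-mortality curve discretization, toxic-unit
    scaling, and the classic one-compartment two-phase model (with
    phase-switching variants) for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
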