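Package: sorbtrans
Title: Sorption Isotherms and Two-Site Nonequilibrium Solute Transport in Soil Columns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the fate of weakly sorbing solutes (such as
    sulfonamide antibiotics) in saturated soil columns. Fits Freundlich and
    Langmuir batch sorption isotherms by their classical linearized
    regressions, forward-simulates conservative-tracer and reactive
    breakthrough curves with a one-dimensional convection-dispersion solver
    coupled to two-site equilibrium/kinetic sorption, and estimates hydraulic
    (pore-water velocity, dispersivity) and sorption (instantaneous-site
    fraction, distribution coefficient, first-order rate) parameters from
    observed breakthrough curves by bounded multistart least squares.
    Includes a seeded synthetic-data generator emulating batch and column
    experimental designs, breakthrough-curve summary metrics, and
    configuration-driven reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
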