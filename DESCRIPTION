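Package: cliodyn
Title: Simulation and Bifurcation Analysis of Population-State Dynamics Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for cliodynamics, the mathematical modelling of long-run
    historical population and state dynamics. Implements two planar
    consumer-resource style ordinary differential equation models: the
    classical Demographic-Fiscal Model (DFM), in which accumulated state
    resources raise the population's carrying capacity until the state
    collapses, and the Demographic-Wealth Model (DWM), in which state wealth
    feeds back on the population through a Holling type-II extraction term
    and can sustain secular cycles. Provides exact Jacobians, closed-form
    equilibrium location and stability classification, Hopf and transcritical
    bifurcation detection with first Lyapunov coefficients, event-aware
    trajectory integration (state collapse handling), limit-cycle period and
    amplitude extraction, one-parameter bifurcation sweeps, a
    paradox-of-enrichment scan, a registry of figure presets, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
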