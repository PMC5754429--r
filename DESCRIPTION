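Package: cellspectrum
Title: Trait-Based Plankton Size-Spectrum Model with Cell-Level Division
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytic and numerical tools for a species-resolved plankton
    size-spectrum model in which unicellular phyto- and zooplankton grow by
    von Bertalanffy uptake, divide by sloppy size control, and interact
    through size-dependent predation. Provides closed-form steady-state
    solvers for the within-species cell-size distributions (idealised and
    general division), the population-growth eigenvalue, the coupled
    predator-prey community steady state whose abundances follow the
    Sheldon power-law spectrum, and a conservative population-balance
    simulator that serves as an independent dynamic check on every
    analytic result.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
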