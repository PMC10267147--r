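Package: knmsim
Title: Cell-Based Simulation of Cardiac Tissue Electrophysiology via
    Kirchhoff Current-Law Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates electrical propagation in cardiac tissue at the
    resolution of individual myocytes. Every cell and its associated
    extracellular compartment are computational nodes coupled through
    intracellular (gap-junction) and extracellular conductances, and the
    network is advanced by first-order operator splitting: a Rush-Larsen
    ionic substep followed by a backward-Euler solve of the coupled
    membrane/extracellular potential system derived from Kirchhoff's
    current law. Includes a homogenized bidomain reference solver on
    matched finite-volume grids, S1-S2 stimulation protocols, conduction
    velocity measurement, spiral-wave reentry detection, and drivers for
    temporal-convergence and gap-junction-resistance sweep experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
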