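Package: egfrsim
Title: Kinetic Simulation of EGFR Signaling in Normal and NSCLC Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ordinary-differential-equation models of the EGFR signaling
    network (Ras/ERK, PI3K/Akt and STAT3 branches) in a normal cell and in a
    non-small-cell lung cancer cell with mutant, over-expressed receptor.
    Provides reaction-network assembly with mass-action and Michaelis-Menten
    rate laws, SBML import and export, stiff ODE simulation, perturbation
    scenarios (PTEN loss, erlotinib inhibition), kinetic feature extraction
    (peak times, sustainment, receptor internalization rates) and calibration
    of under-specified rate constants against published kinetic targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
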