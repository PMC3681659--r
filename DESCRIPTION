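Package: fibrincap
Title: Protein Transport and Hemodynamics in Fibrin-Capped Thrombi
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrated analysis of protein transport through fibrin networks
    covering a stabilized thrombus. Calibrates gel-level physics from permeation
    and photobleaching data (Darcy permeability, fibrin volume fraction, fiber
    radius from the Jackson-James random-fibre relation, hindered diffusion by
    extended-Ogston and effective-medium models, Soumpasis FRAP fitting), solves
    the creeping flow around a composite thrombus (impermeable platelet core,
    Brinkman-permeable fibrin cap) analytically, evaluates the hydrodynamic drag
    on the thrombus, estimates near-core diffusion layers, and transports
    thrombin through the resolved flow with a finite-volume minmod-limited
    advection-diffusion solver. Seeded synthetic-data generators emulate the
    wet-lab measurements so the full pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
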