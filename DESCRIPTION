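Package: glagovsim
Title: Three-Layer Morphoelastic Simulation of Glagov Arterial Remodeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates atherosclerotic remodeling of a coronary artery modeled
    as three concentric incompressible hyperelastic annuli (Neo-Hookean intima,
    fiber-reinforced exponential media and adventitia) in which the intima
    undergoes uniform isotropic growth. Solves the nonlinear pressure-balance
    equation for the deformed geometry at each growth level, produces
    lumen-area-versus-stenosis remodeling curves, locates the critical stenosis
    (interior maximum), contrasts ex-vivo (unpressurized) with in-vivo
    (pressurized) vessel geometry, and fits penalized cubic smoothing splines
    to (stenosis, lumen area) datasets. Includes a synthetic-cohort generator
    emulating histology-style point clouds for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
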