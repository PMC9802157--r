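Package: porocav
Title: Cavitation Bubble Dynamics in Soft Porous Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Continuum-scale simulation of cavitation bubble collapse and
    expansion inside a deformable, fluid-saturated porous medium. Couples
    compressible single-component liquid-vapor flow in the pore network
    (a smoothed barotropic equation of state plus Darcy flow) with the
    linear-elastic response of the solid skeleton (Biot poroelasticity).
    Provides a spherically-symmetric finite-volume solver for the reduced
    density equation, a poroelastic extension of the Rayleigh-Plesset
    equation for the bubble radius (including ultrasonic forcing and
    non-condensable gas), a 2D axisymmetric coupled solver for collapse
    near a rigid wall, and experiment runners with CSV/VTK output.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    grDevices,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
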