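Package: afmtools
Title: Force-Matched Buckingham Force Fields and Thermophysical Property
    Estimation for Molecular Liquids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits Buckingham-class (exp-6 plus point-charge) force-field
    parameters to reference atomic forces by staged weighted least squares
    (force matching), including joint neat/hydrated mixed-phase fits, and
    extracts thermophysical properties from trajectory-derived observables:
    surface and interfacial tension from the pressure tensor, liquid-vapor
    coexistence densities with a cavity-robust two-step slab protocol,
    critical point via the Wegner expansion and the law of rectilinear
    diameters, Antoine vapor-pressure fits and boiling points (including a
    free-energy route through the vaporization free energy), solvation free
    energies, and transport coefficients (Einstein-relation diffusion,
    Green-Kubo viscosity, volume-fluctuation compressibility). A seeded
    synthetic-data module generates every input with known ground truth so
    the full pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
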