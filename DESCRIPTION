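Package: heartloop
Title: Finite-Element Growth Simulation and 3D Morphometry of Heart Tube Looping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A predictive finite-element model of the looping of the embryonic
    heart tube: an elastic cylindrical shell grows between poles held at a
    fixed separation, is tethered dorsally by a progressively released
    attachment (the dorsal mesocardium), and carries opposite left-right
    growth asymmetries at its two poles. Specified anisotropic growth is
    oriented by a polarizer field derived from a morphogen diffusing from the
    venous to the arterial pole; each step the constrained elastic equilibrium
    of the grown shell is computed by minimising residual-strain energy.
    Includes 3D tube morphometry (axis extraction from cross-section
    centroids, tube length, pole distance, RV-LV axis angle, arterial
    rotation, transverse sector, equivalent-circle perimeter, venous
    displacement), a straight/C/flat-S/helix shape classifier, parameter
    sweeps producing phase diagrams, named control and mutant scenarios, and
    mesh/trajectory export (VTK, OBJ, PLY, CSV, JSON).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
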