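Package: bonemodal
Title: Modal Eigenmetrics of Bone Stiffness from Tetrahedral Finite-Element Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a spectral stiffness metric for bones (or any linear
    elastic solid) from tetrahedral finite-element models with heterogeneous,
    density-derived material properties. Assembles sparse stiffness and
    consistent-mass matrices from linear (P1) tetrahedral elements, solves the
    generalized eigenproblem K u = lambda M u for the smallest eigenpairs under
    fixed or fully free boundary conditions (with analytic rigid-body-mode
    deflation), and derives per-mode modal stiffnesses, a truncated
    modal-superposition static stiffness with its location and direction, and
    natural frequencies. Includes readers and writers for VTK legacy and Gmsh
    ASCII tetrahedral meshes, a piecewise ash-density to Young's-modulus law,
    synthetic fixture generators (boxes, cantilevers, gradient-density beams),
    a mesh-convergence check, and CSV/JSON/VTK export of the metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
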