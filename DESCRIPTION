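Package: cellfit
Title: Unit-Cell Parameter Optimization Against Geometric Distance Restraints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Refines crystallographic unit-cell parameters (a, b, c, alpha,
    beta, gamma) of a small-molecule structure model by minimizing the weighted
    discrepancy between inter-atomic distances, recomputed from fixed
    fractional coordinates under a trial cell, and idealized 1,2/1,3 distance
    restraints (SHELX DFIX/DANG). Supports the lattice constraints of all six
    crystal systems, gradient-based (BFGS) and multi-level hill-climbing
    drivers, and iterative alternation between cell optimization and
    restraint-based coordinate regularization. Includes a SHELX RES/INS reader
    and writer with RESI residue scoping and "+filename" includes, and a
    synthetic fixture generator with known ground truth for validation.
    Intended for electron-diffraction (MicroED/3D ED) structure models, where
    detector-distance uncertainty couples strongly with cell parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
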