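Package: scaffoldFE
Title: Voxel Finite-Element Stiffness Design of Porous Tissue-Engineering Scaffolds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Parametric design of cubic unit-cell lattice scaffolds for tissue
    engineering. Generates voxelized scaffold geometries from pore size, fiber
    width, porosity, layout and material, computes their effective Young's
    modulus by small-strain linear-elastic finite-element homogenization on the
    voxel grid (trilinear hexahedral elements, sparse direct or matrix-free
    preconditioned conjugate-gradient solves), sweeps the five design
    parameters (fiber width, porosity, unit cells per layer, layer count,
    material), and classifies each design point into the stem-cell lineage
    stiffness bands (neurogenic, myogenic, osteogenic) used when matrix
    stiffness is the cue directing stem-cell fate.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: Matrix, Rcpp, methods, stats, utils, graphics, grDevices, jsonlite, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
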