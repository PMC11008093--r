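Package: memwrap
Title: Coarse-Grained Simulation of Nanoparticle Wrapping by Lipid Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implicit-solvent coarse-grained molecular dynamics of
    ligand-decorated nanospheres being wrapped by three-bead lipid
    bilayers.  Provides the Cooke-Deserno lipid force field (FENE bonds,
    harmonic angles, WCA repulsion, broad cosine tail attraction), a
    Langevin integrator with a zero-tension lateral barostat and rigid
    nanoparticle dynamics, two interchangeable ligand-receptor coupling
    schemes (an unrestricted distance-dependent pair potential and a
    valence-limited dynamic bond scheme), deterministic seeded builders
    for membranes and Fibonacci-lattice nanospheres, and an analysis
    layer that measures ligand valency, wrapping time, the percent error
    in wrapping time between coupling schemes, and membrane observables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
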