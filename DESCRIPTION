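Package: mtzip
Title: Coarse-Grained Mechanochemical Simulation of Microtubule Sheet-to-Tube Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Particle-level simulator of a growing 13-protofilament microtubule
    whose plus end terminates in an open, outward-curved tubulin sheet. Each
    tubulin monomer is one point mass; seven harmonic interactions
    (longitudinal, lateral and diagonal stretching, longitudinal and lateral
    bending, longitudinal and lateral dihedral bending) define the lattice
    potential. Conformations are relaxed by velocity-Verlet integration with
    kinetic-energy rescaling; growth proceeds through stochastic GTP-dimer
    assembly governed by association thermodynamics, monomer-pair seam closure
    (the sheet-to-tube transition), and GTP-hydrolysis events. The package
    reproduces closure energy barriers and equilibrium energy steppings,
    conformational-cap length estimates, and Tetris-like steady growth, and
    exports trajectories as extended XYZ and PDB.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
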