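Package: loopcsa
Title: Protein Loop Modeling by Conformational Space Annealing of a Hybrid Energy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Ab initio protein loop modeling by global optimization of a hybrid
    energy function that combines physics-based terms (bonded, Lennard-Jones,
    Coulomb, generalized-Born/surface-area solvation) with knowledge-based terms
    (backbone and side-chain torsion statistics, orientation-dependent hydrogen
    bonds, and a distance-binned atom-pair potential of mean force).  Closed loop
    conformations are generated by fragment assembly with analytic tri-axial loop
    closure and evolved by conformational space annealing under a shrinking
    diversity radius.  Includes the evaluation metrics used in loop-modeling
    benchmarks (main-chain loop RMSD, all-atom RMSD under symmetric side-chain
    flipping, environment RMSD) and self-contained generators for perturbed-
    environment test sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
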