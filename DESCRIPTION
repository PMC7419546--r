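Package: membranekit
Title: Trajectory Analysis for Coarse-Grained Lipid Bilayers and Membrane Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Structural and dynamical descriptors of lipid bilayer
    trajectories (area per lipid, area compressibility modulus, density
    profiles and thickness), lateral diffusion via the Einstein relation,
    lipid flip-flop event detection, species-species contact statistics
    with a permutation random-mixing null, single-linkage lipid clustering
    under periodic boundaries, and protein-ensemble analyses (Kabsch
    superposition, RMSF and B-factors, dynamical cross-correlation maps,
    principal component analysis, and a C-alpha anisotropic network
    model).  Includes a synthetic-trajectory generator with known ground
    truth so every estimator can be validated by parameter recovery, plus
    readers and writers for GRO and multi-model PDB coordinate files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    bio3d,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
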