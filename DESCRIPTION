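Package: bindmode
Title: Protein-Ligand Binding-Mode Analysis from Crystal Structures and MD Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to characterise how a small-molecule ligand is recognised by
    a protein across crystal structures and molecular-dynamics trajectories.
    Reads single- and multi-model PDB coordinate files, classifies
    protein-ligand contacts into hydrogen bonds, water-mediated hydrogen
    bonds, nonpolar and electrostatic interactions under configurable
    distance/angle rules, audits crystal-packing contacts by space-group
    symmetry expansion, computes per-frame contact time series, selects
    superposition atoms from persistent contacts, clusters trajectory frames
    by all-pair fitted RMSD with the greedy neighbour-count (Daura)
    algorithm, and compares binding poses by anchored superposition. A
    deterministic synthetic-data generator (planted binding modes, toy
    crystals, interaction-geometry fixtures) lets the whole pipeline be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    jsonlite,
    optparse
Config/testthat/edition: 3
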