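Package: hydronet
Title: Conserved Water Sites and Ligand Recognition Networks in Structural Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of multi-model coordinate ensembles (molecular dynamics
    snapshots or superposed crystal structures) of protein-ligand complexes:
    rigid-body Kabsch superposition, RMSD/RMSF time series, geometric detection
    of hydrogen bonds, salt bridges, metal coordination and T-shaped pi-stacking
    with occupation-frequency statistics, conserved-water-site detection by
    spatial clustering of superposed waters at a 1.8 Angstrom pairing cutoff,
    and graph search for direct and water-mediated recognition paths from a
    bound ligand to metal centers. Includes a seeded synthetic-ensemble
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
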