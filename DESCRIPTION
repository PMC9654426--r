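Package: pienet
Title: Pair Interaction Energy Decomposition and Residue Interaction
    Networks for Protein-DNA Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of residue-residue interactions in protein-DNA
    complexes over molecular-dynamics snapshot ensembles.  Computes
    force-field (Coulomb + Lennard-Jones) pair interaction energies
    between residues with exclusion and 1-4 weighting rules, supports
    segment (conventional residue) and shifted fragment unit schemes,
    decomposes pair energies into backbone/functional subunit and
    hydrogen-bond functional-group contributions, ingests quantum-chemical
    pair-interaction component tables (electrostatic, dispersion, solvent
    screening, charge transfer), averages quantities over snapshot
    ensembles, builds thresholded residue interaction network graphs, and
    compares such graphs with joint-histogram mutual information and
    coefficients of constraint.  A seeded synthetic-data generator
    produces toy duplex-plus-protein complexes and matching component
    tables for testing the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    graphics,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
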