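Package: porescope
Title: Ion-Channel Permeation Analysis from Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("porescope", "developers", role = c("aut", "cre"),
    email = "porescope@example.org")
Description: Analysis of ion and metabolite permeation through wide
    membrane channels such as the voltage-dependent anion channel (VDAC).
    Reads structures (PDB) and trajectories (CHARMM/NAMD DCD or a
    plain-text dialect), defines a pore-axis reaction coordinate from
    reference residues, detects geometric interactions (electrostatic,
    cation pairing, pi-pi, cation-pi, guanidinium stacking, hydrogen
    bonds), counts translocation events across the pore slab, computes
    slice-averaged interaction profiles, occupancy histograms, ion-pairing
    profiles and Boltzmann-inversion free-energy profiles with block
    standard errors, anion/cation selectivity ratios, alignment-column
    conservation statistics, and conductance from current-voltage series.
    Includes a synthetic-data module (toy pore builder and overdamped
    Brownian-dynamics generator with known ground truth) so every stage
    is testable without an MD engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
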