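Package: rpscore
Title: Voxel-Based Deep Scoring of RNA-Protein Docking Decoys
Version: 0.1.0
Authors@R: person("RP", "Score Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Ranks RNA-protein complex structural decoys by native-likeness.
    Parses PDB coordinate files, assigns per-atom types, masses and partial
    charges from configurable tables, extracts the RNA-protein interaction
    interface at a 6 Angstrom cutoff, builds per-residue local coordinate
    frames and 32 Angstrom voxel grids (occupancy, mass, charge channels),
    and scores poses with a sequence-spatial ("4D") convolutional network
    trained by mini-batch gradient descent against interface-RMSD labels.
    Includes a 3D convolutional baseline, a rigid-body synthetic decoy
    generator with controlled RMSD, CAPRI-style evaluation (interface RMSD
    after Kabsch superposition of the protein partners, success rates at a
    4.0 Angstrom threshold), a simplified intermolecular hydrogen-bond
    detector, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
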