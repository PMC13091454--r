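Package: fibrilstab
Title: Solvation Energetics and Geometry of Amyloid Fibril Models
Version: 0.2.0
Authors@R: person("Fibril", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the stabilization free energy of amyloid
    fibril atomic models from buried solvent-accessible surface area and
    atomic solvation parameters. Reads PDB and mmCIF models, expands a
    single fibril layer into an N-layer stack via helical rise and twist
    (including pseudo-2-fold-screw paired protofilaments), computes
    Shrake-Rupley solvent-accessible surface areas, converts per-atom
    buried areas into per-residue and per-chain free energies, models
    polyanion (RNA) binding as charge compensation of lysine, arginine and
    histidine nitrogens, superposes residue segments between folds
    (Kabsch), and assembles a two-axis fibril stability landscape. Includes
    a deterministic synthetic fibril generator and brute-force oracles so
    the full pipeline is testable without downloads.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
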