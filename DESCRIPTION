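Package: cgdock
Title: Coarse-Grained Free-Energy Scoring of Protein-Protein Docking Decoys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks protein-protein docking decoys by an estimated binding free
    energy obtained from constraint-force integration. Complexes are
    coarse-grained to one bead per residue with four particle classes (polar,
    nonpolar, apolar, charged), a rigid-body overdamped Langevin engine samples
    the mean force needed to hold the receptor-ligand centre-of-mass distance
    at a series of windows, and the force profile is integrated (with a radial
    Jacobian correction) to a potential of mean force from which the binding
    free energy is extracted. A staged replicate protocol ranks decoy sets, and
    CAPRI quality measures (fnat, ligand RMSD, interface RMSD, four-tier
    classification) with enrichment and recall/precision reports assess the
    selections. A synthetic-data generator builds toy native complexes, decoys
    spanning all quality tiers, and force profiles from analytically known
    potentials.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    graphics,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
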