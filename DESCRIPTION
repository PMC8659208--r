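Package: mdtriage
Title: Molecular Dynamics Driven Triage of Protein-Ligand Binders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-processing toolkit for molecular dynamics simulations of
    protein-ligand complexes, built around a multi-parameter traffic-light
    rubric for ranking candidate binders of the BRD9 bromodomain.  Computes
    backbone RMSD, per-residue RMSF, radius of gyration, RMSD-based frame
    clustering with representative extraction, and an apo-resemblance
    binding-site filter from trajectories; detects protein-ligand contacts
    frame by frame and summarises them as interaction-fraction fingerprints;
    aggregates externally computed MM-GBSA and per-residue interaction
    energies; converts experimental dissociation constants to binding free
    energies; and combines seven descriptors into an
    Excellent/Good/Intermediate/Bad triage label per compound.  A synthetic
    trajectory and energy-table generator with known ground truth supports
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
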