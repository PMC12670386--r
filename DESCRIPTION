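Package: ligtraj
Title: Receptor-Ligand Trajectory, Docking-Box and Contact Analysis
Version: 0.1.0
Authors@R:
    person("ligtraj", "developers", email = "ligtraj@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for membrane-receptor / small-ligand modelling
    studies: native readers for PDB, GRO and multi-model trajectories,
    Kabsch superposition with RMSD, per-region RMSD-share attribution and
    per-residue RMSF, diketone conformer descriptors (oxygen-oxygen distance,
    cis/trans classification, PCA embedding, k-means clustering with medoid
    conformers), docking search-box construction from transmembrane and
    extracellular C-alpha centroids, docking-pose ingestion and filtering,
    residue-ligand contact occupancy, retention, hydrophobic-contact and
    hydrogen-bond statistics, computational alanine-scanning contact-loss
    metrics, a seeded synthetic receptor-ligand trajectory generator with
    known ground truth, and a staged pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
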