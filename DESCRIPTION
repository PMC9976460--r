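Package: spatiochrom
Title: 3D Chromosome Reconstruction from Hi-C Contacts and Spatiosynteny Statistics
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs three-dimensional single-chromosome models from
    binned Hi-C contact matrices using a coarse-grained beads-on-a-string
    polymer model integrated with damped Newtonian dynamics (Verlet scheme)
    under volume-exclusion, chromatin-tension and Hi-C restraint forces.
    Provides interaction-sphere (IntSph) contact-density profiling with
    radius scans and sigmoid-based radius selection, HiC-Pro sparse matrix
    input, modified-PDB model output, gene-to-bead mapping with ancestral
    linkage group (ALG) classification, microsynteny block detection with
    block randomisation, Fisher-exact chromosome homology tests, the
    Fasano-Franceschini two-dimensional two-sample test, and comparative
    spatial statistics for conserved 3D gene neighbourhoods
    (spatiosynteny). Includes a seeded synthetic-data generator producing
    every input format the pipeline consumes, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    matrixStats,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
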