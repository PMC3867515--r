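Package: pharmensemble
Title: Optimized Linear Combinations of Pharmacophore Hypotheses for
    Ligand-Based Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds per-cluster pharmacophore hypotheses from curated active
    compounds and searches exhaustively for the linear combination of
    hypotheses (an ensemble used under hit-once or hit-twice rules) that
    maximizes the Matthews correlation coefficient, accuracy or recall on
    paired test sets of actives versus decoys and assumed inactives.
    Includes activity curation to a common Ki scale, MOLPRINT-2D atom
    environment and 3D pharmacophore triplet fingerprints with Soergel
    distances, hierarchical clustering with Kelley level selection,
    sphere-exclusion diversity selection, feature-based hypothesis matching
    by Kabsch superposition under an RMSD tolerance, random-combination and
    single universal-hypothesis benchmarks, and a synthetic planted-world
    generator for fully labelled test fixtures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ChemmineR,
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
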