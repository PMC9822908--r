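Package: alsSubtypes
Title: Consensus Non-Smooth NMF Molecular Subtyping of ALS Cortex Transcriptomes
Version: 0.1.0
Authors@R:
    person("alsSubtypes", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Molecular subtype discovery and classification for bulk postmortem
    cortex RNA-seq with locus-specific transposable-element (TE) features.
    Implements locus-level TE feature parsing and filtering, median-of-ratios
    size factors, a closed-form negative-binomial variance stabilizing
    transformation, MAD-based feature selection, a simplified negative-binomial
    Wald differential-expression engine (used for sex-gene removal), non-smooth
    non-negative matrix factorization (nsNMF) with cophenetic-correlation rank
    estimation and replicate consensus subtyping, entropy-based feature scores,
    topological-overlap co-expression modules with eigengene trait association,
    a bootstrap subtype-score classifier with hybrid-state detection and
    hexagonal embedding, Kaplan-Meier / log-rank clinical endpoint analysis,
    and a seeded synthetic-cohort generator so that the full pipeline is
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    Matrix,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
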