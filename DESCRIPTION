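Package: orgslice
Title: Drug-Response Stratification of Organotypic Tumor Slice Cultures
Version: 0.1.0
Authors@R: person("orgslice", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for ex vivo organotypic tumor slice
    pharmacology experiments: immunohistochemistry scoring (Ki-67 index,
    two-score/H-score composites, growth index), baseline-normalized
    time-course trajectories, responder/non-responder classification from
    relative Ki-67 suppression, reference-gene-stabilized normalization of
    qPCR gene cards with differential ranking, 2^-dCt relative
    quantification, and Bliss-independence excess analysis of two-drug
    dose-matrix viability screens. Includes seeded synthetic-cohort,
    gene-card and dose-matrix generators so the full chain is testable
    without tissue data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
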