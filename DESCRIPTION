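Package: g1screen
Title: Analysis of Kinome-Wide siRNA Screens for Radiation-Induced G1
    Checkpoint Activation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of high-content RNAi screens that read out
    ionizing-radiation-induced G1 checkpoint activation from per-cell
    fluorescence intensities. Provides control-anchored single-cell gating
    into per-well responder fractions (loss of phosphorylated RB1, p21
    nuclear positivity, nuclear/cytoplasmic G1 reporter ratio), Z-prime
    plate quality control, z-score hit calling with fold-reduction grading,
    counterscreen filtering and oligonucleotide deconvolution validation,
    knockdown-by-treatment interaction indices for checkpoint and viability
    assays, and hierarchical clustering of per-target phenotype profiles.
    A seeded synthetic-screen generator with planted hits makes every stage
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
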