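Package: seqrep
Title: Multi-Voxel Pattern Analysis of Motor Sequence Representations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A simulation-backed pipeline for studying how finger movement
    sequences are represented in cortical activity patterns. Generates
    constrained finger sequences and synthetic force traces, simulates
    run-structured BOLD time series from a generative pattern model
    (common, sequence-specific, run-common and trial-noise components),
    estimates per-sequence activation patterns with a general linear
    model, classifies them with cross-validated regularized linear
    discriminant analysis, maps decoding accuracy with a searchlight over
    an abstracted cortical sheet, characterises the spatial dimensionality
    of sequence representations, and decomposes pattern variance into its
    generative components.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'seqtask.R'
    'schedule.R'
    'synthgen.R'
    'glm.R'
    'mvpa.R'
    'dimensionality.R'
    'decomposition.R'
    'maps.R'
    'pipeline.R'
    'io.R'
    'seqrep-package.R'
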