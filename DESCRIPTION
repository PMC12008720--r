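Package: taugraph
Title: EEG Functional-Network Graph Measures and Regional Tau PET Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: End-to-end pipeline relating resting-state EEG functional-network
    disintegration to regional tau PET burden in early Alzheimer's disease.
    Provides deterministic EEG preprocessing (polyphase resampling, average
    re-referencing, zero-phase band-pass filtering, epoching, Welch spectra),
    weighted Phase Lag Index (wPLI) connectivity in canonical frequency bands,
    weighted global graph measures in sensor space (Onnela clustering
    coefficient, characteristic path length) with electrode-subset variants,
    region-level PET arithmetic (tracer-specific Centiloid conversion,
    voxel-weighted VOI aggregation, normative tau-positivity thresholds), a
    composable statistical battery (multiple regression, partial Spearman
    correlation, Kruskal-Wallis with Dunn post hoc, minres factor analysis with
    varimax rotation and Thurstone regression scores, FDR adjustment), and a
    seeded synthetic-cohort generator emulating the joint EEG/PET/neuropsych
    structure of a three-group amyloid/tau study so that every stage is
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
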