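Package: mirpanel
Title: Discovery of Circulating miRNA Biomarker Panels from Absolute RT-qPCR Data
Version: 0.1.0
Authors@R:
    person("Panel", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering multi-miRNA biomarker
    panels from serum RT-qPCR profiling. Provides absolute quantification of
    miRNA copy numbers via per-assay standard curves with amplification
    efficiency correction, spike-in normalization of RNA isolation yield,
    hemolysis quality control, global geometric-mean normalization,
    differential expression with FDR control, sequential forward floating
    selection (SFFS) of panel members under repeated stratified two-fold
    cross-validation with ridge-stabilised logistic regression, and
    frozen-model evaluation (ROC/AUC, operating-point selection, confusion
    metrics with Wilson intervals, and ordered-trend tests). A synthetic
    cohort generator emulates the plate-level data-generating process so that
    every stage is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
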