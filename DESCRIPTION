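Package: wmtopo
Title: Working-Memory Task Connectome Topology, Polygenic Scoring, and
    Moderation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for weighted small-world
    topology of working-memory task functional connectomes in case,
    sibling, and control cohorts. Generates synthetic multi-subject ROI
    time series with group-structured covariance, builds covariate-
    corrected Fisher-z connectivity matrices from task blocks, computes
    density-thresholded weighted graph metrics normalized against
    degree-preserving null ensembles, synthesizes metric-versus-density
    curves into scalars for group statistics, performs genotype quality
    control with LD clumping and multi-threshold polygenic risk scoring
    with first-principal-component synthesis, and fits single- and
    dual-moderator interaction regressions with bootstrap inference.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    Matrix,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
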