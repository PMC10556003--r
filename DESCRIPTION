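Package: mciTrajectory
Title: Cluster-Trajectory Atlases for Predicting Conversion from MCI to
    Alzheimer's Dementia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models progression from mild cognitive impairment (MCI) to
    Alzheimer's dementia (AD) from low-dimensional trajectories of regional
    cortical thickness. Regional thickness z-scores (Desikan-Killiany-Tourville
    cortex, 62 regions) are embedded into a 2-D space by a neighbor-graph
    manifold reduction rotated onto its principal axes, the embedding is
    partitioned by an equal-size k-means variant, subjects' annual visit
    sequences become discrete cluster trajectories, and a probabilistic atlas
    maps each trajectory to an empirical conversion probability. Includes
    longitudinal visit binning, normative z-scoring, stratified repeated
    cross-validation with ROC/AUC model selection, a synthetic cohort
    generator for fully reproducible end-to-end runs, and a command-line
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'roster.R'
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'io.R'
    'synthetic.R'
    'preprocess.R'
    'embedding.R'
    'clustering.R'
    'atlas.R'
    'evaluation.R'
    'pipeline.R'
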