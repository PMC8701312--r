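Package: longicort
Title: Longitudinal Surface-Based Cortical Thickness Analysis with
    Random-Field-Theory Cluster Inference and Transcriptomic Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal surface-based morphometry: per-vertex
    symmetrized percent change of cortical thickness, surface-based
    smoothing, mass-univariate general linear models with nested step-up
    model selection, random-field-theory cluster inference for
    nonisotropic fields with a permutation oracle, cluster-wise
    brain-behavior correlation with false-discovery-rate control, and
    gene-expression decoding of statistical maps with hypergeometric
    gene-set enrichment. Includes a synthetic-cohort generator (icosphere
    template meshes, two-timepoint thickness maps with planted group
    effects, skewed behavioral item responses, spatial expression
    matrices) so the full pipeline can be exercised and calibrated
    without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
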