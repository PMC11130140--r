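Package: qcscore
Title: Quantitative Continuous Scoring of Membrane-Marker Immunohistochemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative continuous scoring (QCS) of membrane-marker
    immunohistochemistry such as HER2. Computes per-cell DAB optical density on
    subcellular compartments from stained regions of interest (colour
    deconvolution, seeded-watershed instance segmentation, membrane band
    extraction), derives per-patient readouts (optical-density quantiles,
    percentage and density of OD-positive tumour cells, binary and continuous
    spatial proximity scores, stromal TIL density), consolidates redundant
    readouts, and stratifies patients by bootstrap-stabilised cut-point
    optimisation with repeated cross-validation and permutation-based empirical
    log-rank p-values. Includes a synthetic cohort and image generator with
    ground truth so that the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    survival,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
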