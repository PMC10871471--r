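Package: glucestr
Title: GluCEST Brain Imaging Simulation, Correction, and Cohort Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for glutamate-weighted chemical exchange saturation
    transfer (GluCEST) MRI analysis at 7T: a two-pool (water + glutamate
    amine) Bloch-McConnell z-spectrum simulator, synthetic single-slice
    phantoms and study cohorts with known ground truth, WASSR-based B0
    field mapping, multi-flip-angle relative-B1 mapping, B0/B1-corrected
    percent-contrast maps, ROI summarization over gray/white matter and
    cortical regions, and cohort statistics (exact Wilcoxon rank-sum group
    comparisons, age regressions, and volume-contrast correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    RNifti,
    yaml,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
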