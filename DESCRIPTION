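Package: organoidScreen
Title: Cell-Type-Specific Toxicity Analysis for 3D Midbrain Organoid Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for high-content toxicity screens of
    3D human midbrain organoids in 96-well plates. Quantifies dopaminergic (TH+)
    and pan-neuronal (Map2+) content from multi-channel confocal image stacks via
    organoid region detection and gating, background correction (Gaussian
    subtraction and sliding-parabola top-hat), cell-ROI segmentation and
    raw-channel intensity integration; processes ATP-luminescence viability with
    percent-of-control plate normalization; fits four-parameter logistic
    dose-response curves with IC50 extraction; computes screening statistics
    (pooled-variance t-tests with Bonferroni-Dunn correction) and an emulated
    sample-attrition survival curve. Includes a synthetic plate and image
    generator with exported ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
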