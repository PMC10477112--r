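Package: plaq
Title: Quantification of Proximity Ligation Assay Signals in 3D Confocal Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reimplements, as reusable and tested R functions, an image-analysis
    workflow for quantifying proximity ligation assay (PLA) puncta in two-channel
    3D confocal z-stacks: per-cell PLA-area to nucleus-area ratios (Gaussian
    pre-blur, best-focus plane selection, Li minimum cross-entropy and Triangle
    auto-thresholding, 3D threshold application, size filtering), percentage of
    GFP-marked organelle volume occupied by PLA signal, group statistics with
    ROUT robust outlier removal and Student's t test, delta-delta-CT relative
    quantification and below-detection-limit censoring, and an algebraic
    decomposition bounding the C-terminal-fragment share of a composite PLA
    signal. A seeded synthetic-scene generator with exact voxel ground truth
    stands in for microscopy data so every stage is testable.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tiff,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
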