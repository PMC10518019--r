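Package: scmst
Title: Single-Cell Multiplex Spatial Transcriptomics (scMST) Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of serial single-molecule FISH (scMST)
    acquisitions: synthetic multi-round phantom generation with full ground
    truth, HCR-style probe tiling, illumination correction and 3D median
    filtering, integer inter-round registration, 3D spot detection with
    K-means intensity triage, seeded 3D watershed cell segmentation and
    per-cell transcript counting, two-stage z-score normalization,
    cosine-distance hierarchical clustering of cells into subpopulations,
    co-expression cell selection, and pseudo-colored spatial back-mapping
    with display-only stitching of fields of view.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    cluster,
    jsonlite,
    yaml,
    tiff,
    png,
    Matrix,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    mclust
Config/testthat/edition: 3
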