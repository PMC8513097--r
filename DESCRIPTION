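Package: mgmorph
Title: Three-Dimensional Microglia Morphometry and Marker Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Single-cell three-dimensional morphometry of microglia from
    confocal z-stacks: Huang fuzzy-entropy auto-thresholding and
    connected-component particle filtering for single-cell segmentation;
    volume, iso-surface area, ramification index, convex-hull polarity
    index and mean marker intensity; topology-preserving 3D
    skeletonization with branch-level metrics (branch number, tree
    length, average branch length); soma-ROI quantification of CD68 area
    fraction and punctate lipofuscin autofluorescence (particle counts,
    densities and area fractions) with cohort-fixed reference
    thresholds; behavioral sociability/preference indices with
    chance-level tests and ROUT robust outlier screening; and a
    synthetic-cohort generator producing confocal-like stacks of
    branched cells with exact ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    jsonlite,
    mgcv,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
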