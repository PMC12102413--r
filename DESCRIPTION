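Package: wsicoloc
Title: Hierarchical Point Colocalization Between Re-Stained Whole Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps point annotations (nucleus or mitosis coordinates) between
    pyramidal whole slide images of the same tissue section that has been
    re-stained and re-scanned, possibly on different scanners. Registration is
    hierarchical: tissue is segmented on overview levels, a coarse similarity
    transform is estimated by Mattes mutual information with adaptive
    stochastic gradient descent, the transform is extrapolated to the base
    layer, and refined either per grid tile (for clustered annotations) or per
    annotation patch (for sparse annotations). Includes a synthetic slide-pair
    generator with exact ground-truth correspondences and an SSIM-based
    colocalization evaluation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    EBImage,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png
Config/testthat/edition: 3
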