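Package: vesselac
Title: Vessel Segmentation by Localized Active Contours with a Vascular Vector Field
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Level-set active contour segmentation of tubular (vascular)
    structures in 2D grayscale images. The data term is a localized region
    energy built from kernel-weighted interior/exterior fitting means, which
    tolerates intensity inhomogeneity; a multiscale Hessian vesselness measure
    supplies a vascular vector field that pulls the contour along thin and
    weak vessels. Includes automatic contour initialization from the
    vesselness map, narrowband evolution with steady-point freezing, a
    modified root-mean-squared-error (MRMSE) contour metric, Dice overlap,
    and a deterministic synthetic vascular phantom generator with ground
    truth for verification.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    EBImage,
    mgcv,
    png,
    tiff,
    yaml,
    jsonlite,
    withr,
    stats,
    grDevices,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
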