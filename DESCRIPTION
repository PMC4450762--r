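Package: phasesnake
Title: Active Contour Segmentation and Tracking of Single Cells in
    Phase-Contrast Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments and tracks the boundary of a single cell (e.g. a
    lymphocyte) in phase-contrast microscopy image sequences with a
    parametric active contour (snake).  The external force is a vector
    field convolution (VFC) field computed from a sparse binary feature
    map obtained by morphological gray-scale reconstruction (hole
    filling), Laplacian-of-Gaussian filtering, zero-crossing detection
    and small-component removal.  The contour is initialized close to
    the phase halo by histogram thresholding of the reconstructed region
    of interest, and propagated frame to frame for tracking.  Includes a
    gradient-vector-flow (GVF) baseline, a synthetic phase-contrast
    scene generator with ground-truth masks, and Jaccard-based
    evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    mgcv,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
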