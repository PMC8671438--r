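Package: patchseg
Title: Self-Supervised Marker-Controlled Single-Cell Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains a convolutional encoder-decoder to segment individual
    cells from multi-channel microscopy fields without any manual pixel
    annotation. Each cell is represented by a marker (a nucleus position);
    the network segments one cell per marker-centered image patch and is
    optimized with a self-supervised objective that rewards segmented area,
    penalizes inconsistent claims on pixels shared by overlapping patches,
    and penalizes segmentation outside a binary cell-area mask obtained by
    graph-cut energy minimization (fluorescence) or a scribble-trained pixel
    classifier followed by graph cut (bright-field). Includes
    difference-of-Gaussians nucleus detection, an image-to-nucleus
    translation model for computing markers when no nucleus channel was
    acquired, whole-field assembly of per-patch predictions, mean
    intersection-over-union evaluation, and a deterministic synthetic-scene
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    tiff,
    randomForest,
    EBImage,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
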