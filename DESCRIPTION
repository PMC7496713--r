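Package: swdgrid
Title: Grid-Based Convolutional Detection of Spotted-Wing Drosophila in
    Sticky-Trap Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detection and sexing of the spotted-wing drosophila
    (Drosophila suzukii) in photographs of red sticky traps. Implements a
    fully convolutional grid classifier (a truncated residual backbone
    with a 1x1-convolution head emitting a per-cell class-probability
    map), patch-based training with dihedral augmentation and a two-phase
    Adam schedule, tiled full-image inference with stitching,
    class-agnostic 3x3 non-maximum suppression, and a point-based
    evaluation protocol (50-pixel centroid matching, precision-recall
    curves and their area under the curve). Ships a synthetic sticky-trap
    scene generator so the whole pipeline can be exercised end-to-end
    without field imagery, readers and writers for Pascal VOC XML
    annotations and detection CSV files, and a small command-line
    front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    xml2,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: C++17
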