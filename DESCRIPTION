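Package: stomatadetect
Title: Patch-Based Stomata Detection and Density Estimation from Leaf Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated workflow for detecting stomata in light-microscope
    images of leaf epidermal impressions and converting detections into
    stomatal densities. Micrographs are divided into overlapping 120x120 pixel
    windows by a sliding-window scan, each window is scored by a small
    convolutional patch classifier (trained with Adam, dropout and dihedral
    data augmentation by the package's own backend), confident windows are
    merged into stoma coordinates by flat-kernel mean-shift clustering, and
    detections are evaluated against ground-truth annotations with one-to-one
    matching, precision/recall/F threshold sweeps, count accuracy and a
    computed-versus-manual counts regression. A seeded synthetic micrograph
    generator renders epidermis-like backgrounds, elliptical stomata with
    pore and guard-cell structure, and negative-class artifacts with exact
    annotations, so the full pipeline is testable end to end without
    microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
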