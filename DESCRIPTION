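Package: dmar
Title: Metal Artifact Reduction for Dental CT by Adaptive Local
    Thresholding and Prior-Image Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and correction of metal artifacts in dental
    computed tomography. Provides polychromatic forward projection of
    material-label phantoms, filtered backprojection and SART
    reconstruction, projection-domain metal-trace segmentation by global
    thresholding refined with adaptive local statistics, prior-image
    generation by fusing a streak-free and a metal-free image, sinogram
    replacement, and quantitative evaluation by windowed structural
    similarity on regions of interest.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
NeedsCompilation: yes
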