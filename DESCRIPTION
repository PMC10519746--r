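Package: holopheno
Title: Stain-Free Cell Phenotyping from Holographic Quantitative Phase Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for label-free phenotyping of
    rolling cells imaged by off-axis holographic flow cytometry. Provides a
    synthetic generator of rotating-cell quantitative phase maps (QPMs) and
    their off-axis hologram encodings; numerical hologram reconstruction
    (Fourier demodulation, angular-spectrum refocusing with Tamura-coefficient
    autofocus, reference compensation, quality-guided phase unwrapping); a
    37-feature hybrid descriptor of each QPM combining optical-path-length
    statistics, 2D morphology, gray-level co-occurrence texture and
    box-counting fractal geometry; a three-level hierarchical shallow-network
    classifier with per-cell majority voting; and evaluation utilities
    (split construction, recall and accuracy, PCA with Fisher's criterion,
    grouped feature correlation, ReliefF ranking, path-probability
    composition).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    stats,
    utils,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
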