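Package: polypscan
Title: Polyp Detection in Endoscopy Frames by Color-Wavelet and CNN Feature Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sliding-window detection of gastrointestinal polyps in endoscopy
    frame sequences. Each 227x227 window is described by 144 color-wavelet
    texture features (per-channel 3-level discrete wavelet transform,
    gray-level cooccurrence matrices of the middle detail subbands in four
    directions, and four Haralick statistics) fused with the 4096 activations
    of the second fully connected layer of an AlexNet-style convolutional
    network, and classified by a linear support vector machine. Per-window
    decisions are aggregated into a single averaged polyp marker per detected
    region. Includes a seeded generator of synthetic endoscopy-like fixtures
    with ground-truth polyp ellipses, so the whole pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    png,
    jpeg,
    tiff,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
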