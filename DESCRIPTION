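Package: mgmorph
Title: Microglial Morphometrics from Fluorescence Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Threshold-based segmentation of immunofluorescence micrographs
    of microglia (Gaussian blur, mean threshold, physically derived
    small-object removal, hole filling, border clearing), per-cell geometric
    morphometrics (area, perimeter, circularity, solidity, aspect ratio),
    cell-density quantification, and boundary-based shape-mode modeling
    (equal-arc contour resampling, registration, PCA and k-means clustering)
    with frequency heat-map summaries. Includes a seeded synthetic-micrograph
    generator with ground-truth masks for end-to-end validation, the
    accompanying statistical battery (Welch-gated t-tests, F-tests of
    variance, coefficient of variation, Kruskal-Wallis with Dunn's post hoc
    test, a four-test normality suite with QQ data), and comparative
    cycle-threshold (2^-ddCt) relative expression analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    nortest,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
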