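Package: lfaquant
Title: Quantitative Image Analysis of Lateral Flow Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end densitometry for lateral flow assays (LFA) and other
    band-based test strips: image loading and non-destructive editing,
    region-of-interest gridding with automatic inter-line background
    rectangles, per-strip background correction by histogram thresholding
    (Otsu, Li cross-entropy, triangle, empirical quantile), per-line
    intensity extraction, intensity-table management, calibration-curve
    fitting (linear, local polynomial, additive spline) with limits of
    blank, detection and quantification, and inverse prediction of analyte
    concentration. Includes a deterministic synthetic strip-image generator
    for validation and a command-line workflow for headless analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    png,
    tiff,
    EBImage,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
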