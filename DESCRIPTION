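Package: mifcal
Title: Cross-Microscope Calibration of Multispectral Immunofluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to measure and correct illumination-intensity and
    spectral-sensitivity differences between multispectral whole-slide
    immunofluorescence (mIF) microscopes. Reduces tiled multi-layer image
    stacks ("high-power fields") to average tissue-flux spectra, fits a
    sequential multiplicative calibration model with sample- and
    microscope-specific amplitude and per-layer profile factors, decomposes
    microscope profiles into illumination, broadband-filter and
    narrowband-filter contributions, quantifies residual variance and
    layer-projected covariance, validates generalization of the microscope
    factors by exhaustive subset bootstrap, and standardizes raw images to a
    reference microscope before non-negative least-squares spectral
    unmixing. Includes a synthetic-data generator with known ground-truth
    factors so the full pipeline can be exercised and validated without
    proprietary scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    EBImage,
    jsonlite,
    optparse
Config/testthat/edition: 3
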