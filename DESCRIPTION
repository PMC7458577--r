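Package: planimetr
Title: Wound Planimetry from Grid-Calibrated Boundary Tracings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated planimetry of chronic-wound boundary tracings drawn on
    a transparent centimetric-grid ruler and scanned to a raster image. The
    pipeline binarizes the scan, self-calibrates the pixel scale from the
    1 cm grid, removes the grid strokes, closes and flood-fills the traced
    boundary, and measures area, perimeter and principal axes of the wound
    region. Classical bedside estimators (rectangle C x L and the Kundin
    ellipsoidal coefficient 0.785), manual grid-square counting, weekly
    percentage-contraction statistics with healing-predictor classification,
    and method-comparison error summaries are included, together with a
    synthetic trace generator with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
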