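Package: chromaval
Title: Colorimetric Assay Strip Reading and CLSI Method Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reads colorimetric test-strip device images and validates the
    resulting quantitative assay against clinical laboratory standards.
    Provides a synthetic device-image generator with known ground truth,
    reaction-pad region-of-interest detection, color-space feature extraction
    (RGB, XYZ, CIELAB, HSV; mean/median/mode per channel), and low-order
    polynomial calibration of analyte concentration.  Implements the CLSI
    method-validation statistics used to characterise such a device: EP05
    balanced nested ANOVA variance components and precision estimates, EP17
    nonparametric limit of blank and limit of detection, EP06 polynomial
    linearity assessment, EP07 interference screening, EP09 predicate
    comparison with distribution-free bias confidence intervals, and EP25
    shelf-life significance screening.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    png,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
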