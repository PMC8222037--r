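Package: steroidMSI
Title: Quantitative MALDI Mass Spectrometry Imaging of Derivatized
    Corticosteroids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative MALDI mass spectrometry imaging of
    corticosteroids after on-tissue Girard hydrazone derivatization.
    Computes derivative and adduct m/z values from molecular formulas,
    reads and writes centroided imzML/ibd datasets, extracts ion images
    with a fixed m/z tolerance window, segments tissue sections and
    on-tissue calibration spots, normalizes the analyte against a
    sprayed internal standard, fits calibration curves with
    lipid-content covariates to quantify ion-suppression effects, and
    back-calculates tissue concentrations. A synthetic-data generator
    emulates the slide layout of an on-tissue dilution-series
    experiment with full ground truth, so every pipeline stage is
    testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    xml2,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
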