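Package: qamskit
Title: Single-Marker Multi-Component Quantification (QAMS) for HPLC-DAD Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of multi-components by single
    marker (QAMS) in multi-wavelength HPLC-DAD chromatography: synthetic
    chromatogram generation with exponentially-modified Gaussian peaks,
    peak detection and trapezoidal integration with chord baseline
    correction, system-suitability metrics (theoretical plates,
    resolution), external-standard calibration with LOD/LOQ estimation,
    relative correction factors by the multipoint method,
    relative-retention-time peak localization, QAMS content calculation
    with external-standard comparison, and a method-validation battery
    (precision, stability, repeatability, recovery, robustness).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
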