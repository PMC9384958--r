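Package: lfaquant
Title: Quantitative Image Analysis of Lateral Flow Assay Strips
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Densitometric quantification of lateral flow assay (LFA) strip
    images, modelled on low-cost CMOS strip readers for sputum neutrophil
    elastase. Extracts an averaged intensity profile from a strip image,
    locates the test and control lines by windowed minimum search, computes
    background-normalised intensity ratios, fits a quadratic calibration
    curve, inverts it to estimate unknown analyte concentrations with
    censoring at the working-range limits, estimates a limit of detection,
    and classifies exacerbation risk. A synthetic strip phantom generator
    with known ground truth makes the whole pipeline testable without
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
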