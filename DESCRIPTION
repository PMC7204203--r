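Package: qamskit
Title: Single-Marker Multi-Component Quantification (QAMS) for Liquid
    Chromatography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the quantitative-analysis-of-multi-components-by-
    single-marker (QAMS) workflow for liquid chromatography: linear
    calibration of detector response against injected mass, relative
    correction factors by the multipoint and slope methods, peak
    assignment by relative retention time against an internal reference,
    quantification by the external-standard and both QAMS routes,
    method-validation statistics (RSD, spike recovery, Pearson method
    agreement), and geometric method transfer between chromatographic
    systems.  Ships a seeded synthetic peak-table and chromatogram
    generator calibrated to published measurements of five flavonoid and
    phenolic markers (ethyl gallate, astragalin, quercetin, luteolin,
    kaempferol) in longan (Dimocarpus longan) leaves, so the whole
    pipeline is testable without an instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
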