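Package: gfbsense
Title: Real-Time Fluorescence Sensing Analytics for Filtration
    Barriers-on-Chip
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computational toolkit for quantifying barrier function in
    membrane-based organ-on-chip devices (for example a
    glomerulus-on-chip) from a two-channel epifluorescence sensor.
    Provides four-parameter logistic calibration of pixel intensity to
    tracer concentration with confidence intervals, sensitivity regions
    and error propagation; per-pixel flat-field illumination correction;
    conversion of background-subtracted sensor frames into per-channel
    concentration time series and diffusion percentages; a lumped
    physics model of trans-membrane transport (wall shear stress,
    Darcy flux, hydrostatic and osmotic pressure, steady-state filtrate
    concentration, permeability estimation and first-order transient
    response); and a synthetic-chip simulator that renders ground-truth
    frames and whole experiments so the full pipeline can be validated
    without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
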