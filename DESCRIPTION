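Package: erkpulse
Title: Quantification of Single-Cell ERK Activity Pulses from Ratiometric
    FRET Time-Lapse Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying pulsatile ERK activity in single cells
    from two-channel (CFP, FRET/YFP) time-lapse imaging of FRET biosensors
    such as EKAREV-NLS. Provides ratiometric image processing (background
    subtraction, maximum intensity projection, median filtering,
    intensity-modulated display rendering), per-cell trace extraction and
    smoothing, fitting of each trace to a flat line or a multi-peak
    max-composition model of cosine-shaped pulses with ERK-pulse+/-
    classification, pulse metrics (frequency, duration, amplitude),
    temporal autocorrelation, detection of pulse propagation between
    adjacent cells with velocity estimates, nonparametric group statistics
    (Mann-Whitney U, Steel-Dwass, chi-square with Benjamini-Hochberg
    adjustment), and a synthetic-data generator that produces ground-truth
    pulse trains, noisy traces, propagating-wave scenes and rendered
    two-channel movies for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
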