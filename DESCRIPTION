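Package: nirsfa
Title: Chemometric Prediction of Beef Fatty Acid Composition from
    Near-Infrared Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calibrating and validating near-infrared reflectance
    (NIRS) models of the fatty acid composition of freeze-dried beef, for the
    total lipid and the phospholipid fraction. Implements the spectral
    pre-treatment operators used in meat NIRS work (offset baseline, area
    normalization, standard normal variate, detrending, multiplicative and
    extended multiplicative scatter correction, Savitzky-Golay and Norris gap
    derivatives) with a parser for pre-treatment chain specifications, NIPALS
    partial least squares regression with Hotelling outlier screening,
    calibration diagnostics (SEC, SEP, R2, RPD, Consistency), lipid-fraction
    arithmetic, and a seeded synthetic-data generator that emulates the
    concentration distributions and spectral shape of a freeze-dried beef
    study so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
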