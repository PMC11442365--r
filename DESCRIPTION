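Package: dyadsync
Title: Movement Synchrony in Dyadic Interactions from Motion Energy Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies nonverbal movement synchrony between two interacting
    people from video. Motion energy analysis (MEA) converts per-person regions
    of interest into frame-differenced movement time series with a data-driven
    noise threshold; windowed cross-lagged correlation (WCLC) with peak-picking
    segments the interaction into leader-attributed synchrony intervals bounded
    at a five-second lag; per-dyad summaries (total, patient-led and
    clinician-led synchrony, the leading variable, and mean time-lags) feed a
    correlational and hierarchical-regression analysis layer with partial
    correlations and extreme-value screening. A coupled-dyad simulator with
    known ground truth (bout structure, leader, lag, planted severity effects)
    validates every stage end-to-end, including rendering synthetic videos for
    round-trip MEA recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
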