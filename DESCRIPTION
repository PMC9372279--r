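Package: dryerp
Title: Signal Quality and Usability Analysis for At-Home Dry-EEG ERP Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying event-related potential (ERP) data quality in
    longitudinal, self-administered dry-EEG studies. Simulates multi-session
    oddball and flanker recordings with known ground truth; band-pass filters,
    epochs and baseline-adjusts continuous EEG; applies a staged per-channel
    epoch-rejection procedure (absolute amplitude, correlation to the session
    average, and z-scored temporal/spectral metrics including the Hurst
    exponent); computes Standardized Measurement Error (SME) curves over
    cross-session trial aggregation; projects the number of at-home sessions
    needed to match wet-EEG reference precision; and scores usability
    (adherence accounting, System Usability Scale, Mann-Whitney U comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
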