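Package: murinecv
Title: Cardiovascular Autonomic Analysis for Murine ECG and Blood Pressure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cardiovascular autonomic function in mice
    from electrocardiogram and arterial blood pressure recordings: R-peak
    detection and artifact screening, heart rate variability in the time
    (SDNN, RMSSD), non-linear (Poincare SD1/SD2) and frequency domains
    (Lomb-Scargle periodogram with murine LF 0.10-1.00 Hz and HF 1.00-5.00 Hz
    bands), sequence-method baroreflex sensitivity, QT measurement on
    ensemble-averaged beats with Mitchell's murine rate correction, and
    three-way factorial group statistics (genotype x sex x age) with
    Sidak-adjusted contrasts between groups differing by one factor.
    Includes generators for synthetic beat series, coupled blood pressure and
    ECG waveforms with known ground truth, for validation without animal
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    signal,
    car
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    withr
Config/testthat/edition: 3
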