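Package: mcbp
Title: Cuffless Blood-Pressure Estimation by Voxel Monte Carlo Photon
    Transport and Photoplethysmography Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates near-infrared photon transport through a voxelized,
    heterogeneous finger model whose digital artery dilates with arterial
    pressure, producing a blood-pressure to detected-photon-intensity lookup
    table for transmission and reflection probe geometries.  Fingertip
    photoplethysmography (PPG) recordings are bandpass filtered, systolic
    peaks and pulse onsets are detected, and the measured beat intensities
    are calibrated onto the simulated intensity scale with gradient-boosted
    tree regression, then inverted to systolic, diastolic and mean arterial
    pressure.  Includes Bland-Altman, AAMI and BHS compliance checks, a MAP
    error-grid classifier, and a seed-deterministic synthetic cohort and PPG
    generator so the whole pipeline can be exercised without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    e1071,
    xgboost,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
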