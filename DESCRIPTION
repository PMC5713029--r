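Package: nfeemd
Title: Heart-Rate Estimation from Motion-Corrupted Wrist Photoplethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Robust heart-rate estimation from a single photoplethysmography
    (PPG) channel recorded at the wrist together with tri-axis acceleration,
    during intense physical activity. Motion artifacts are detected from the
    acceleration periodograms, artifact spectral peaks are removed from the
    PPG spectrum, and windows where the cardiac peak is masked are recovered
    with a cascade of second-order IIR single-notch filters or with ensemble
    empirical mode decomposition followed by singular spectrum analysis.
    A per-window tracking state machine with grey-model (GM(1,1)) assisted
    calibration keeps the estimate on track when the heart rate drifts while
    the spectrum is unusable. Includes readers for the IEEE Signal Processing
    Cup record layout and plain CSV, a synthetic record generator with known
    beat-per-minute trajectories for validation, and agreement metrics
    (average absolute error, Bland-Altman limits of agreement, Pearson
    correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
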