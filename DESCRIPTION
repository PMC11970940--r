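Package: hrvstress
Title: PPG Signal Conditioning, HRV Feature Extraction and Decision-Tree
    Stress Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying mental stress from photoplethysmography
    (PPG): zero-phase Butterworth high-pass conditioning and per-window
    normalization of raw PPG, systolic peak detection and RR-interval
    derivation, a 34-parameter heart-rate-variability feature set
    (time-domain, relative time-domain, frequency-domain via Welch spectra of
    the interpolated tachogram, and nonlinear: Poincare SD1/SD2, sample
    entropy, Higuchi fractal dimension), a three-level CART stress
    classifier, cross-device agreement statistics (RR regression, windowed
    Pearson overlay, FFT spectrum correlation, STFT band energies), a
    windowed end-to-end protocol pipeline with per-phase stress scores and
    DASS-21 regressions, and a synthetic-data module that generates RR
    series with controlled LF/HF spectral structure, rendered PPG waveforms,
    labeled three-class feature tables and full six-phase protocol sessions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    rpart,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
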