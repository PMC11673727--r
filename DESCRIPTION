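Package: ibaemg
Title: Integral-Based Assistance Indices for Human-Exoskeleton EMG Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies the physical human-exoskeleton interaction from paired
    surface-EMG recordings using integrated-EMG (iEMG) based indices. Provides
    the full offline processing chain (30-400 Hz Butterworth band-pass,
    rectification, 2.5 Hz low-pass envelope, 95th-percentile MVC
    normalization), task-phase segmentation from joint-rotation signals with
    hysteresis thresholds, phase-wise time normalization of paired
    no-exoskeleton/exoskeleton trials, the per-sample interaction trend signal
    and its assistive (AII), resistive (RII) and overall (OII) interaction
    indices, the classical percentage-variation indices and amplitude
    distribution diagnostics used to validate them, and a synthetic trial
    generator with closed-form ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
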