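Package: wavetrain
Title: Wave-Train Electrical Activity Analysis for Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects wave trains (time- and frequency-localized bursts of
    power spectral density) in surface electromyogram envelopes as local
    maxima of smoothed complex Morlet wavelet spectrograms, measures their
    central frequency, maximal PSD, duration in periods and bandwidth, and
    compares groups of subjects through range-scan AUC diagrams: 2D lower
    by upper bound grids of the area under the ROC curve of per-subject
    wave-train rates, and 3D multi-resolution stacks with Sidak-form
    Bonferroni-corrected Mann-Whitney significance masks. Includes the
    full preprocessing chain (notch, zero-phase band-pass, Hilbert
    envelope, decimation), an iterative parameter-box refinement loop, a
    Welch-spectrum group comparison baseline, and a synthetic cohort
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
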