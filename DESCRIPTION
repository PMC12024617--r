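Package: radarsomno
Title: Event-Level Sleep Apnea Detection from FMCW Radar Respiration Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for contactless, event-level detection of
    sleep apnea and hypopnea from frequency-modulated continuous-wave (FMCW)
    radar. Includes a multipoint-scattering radar simulator with coupled
    breathing and blood-oxygen physiology, the radar signal-processing chain
    (range FFT, phase unwrapping, Butterworth filtering, channel selection,
    downsampling), a debounced six-state bed-occupancy machine, a multitask
    1D U-Net segmenter with squeeze-and-excitation blocks and a multihead
    self-attention bottleneck trained with Dice and MAE-plus-correlation
    losses, and the full event-level (IOU matching, precision/recall/F1) and
    recording-level (respiratory event index, AASM severity grading,
    Bland-Altman agreement) evaluation suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
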