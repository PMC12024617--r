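# radarsomno

Contactless, event-level detection of sleep apnea and hypopnea from
frequency-modulated continuous-wave (FMCW) radar.

Obstructive sleep apnea is usually diagnosed with polysomnography, which is
expensive, uncomfortable, and unsuitable for screening or long-term home
monitoring. A bedside millimetre-wave radar senses chest-wall displacement
without contact: breathing modulates the phase of the radar echo by
`4π·d(t)/λ`, so sub-millimetre respiratory motion is visible in the phase of
the range–time matrix. `radarsomno` turns that signal into *event-level*
diagnoses — start and end times of individual apnea/hypopnea events — rather
than coarse per-segment risk scores, and grades recordings by the
respiratory event index (REI, events per hour of time in bed) on the AASM
scale.

The package is a full, self-contained pipeline:

* **Radar simulator** — a multipoint-scattering model of the breathing body
  (`scene_script()`, `synthesize_if_signal()`): scripted apnea ("complete
  cessation") and hypopnea ("airflow reduction exceeding 30%") events,
  SpO₂ desaturations lagged 5–20 s with depth ∝ event duration, bed
  entry/exit scenes, configurable SNR. Every downstream stage is testable
  without any clinical data.
* **Signal processing** — per-chirp range FFT, phase unwrapping, third-order
  0.1 Hz Butterworth high-pass, respiratory-band channel ranking, 50→10 Hz
  decimation (`build_range_time_matrix()`, `extract_resp_channels()`).
* **Bed occupancy** — a calibrated three-zone range partition and a debounced
  six-state machine that gates segmentation on the Lie-in-Bed state
  (`calibrate_zones()`, `segment_recording()`).
* **Segmentation model** — a multitask 1D U-Net with squeeze-and-excitation
  blocks and a positional-encoded multihead self-attention bottleneck, with
  twin decoders for per-sample event probability and scaled SpO₂
  (`build_model()`, `train_segmenter()`). Trained with batch-level Dice loss
  for events plus MAE + Pearson-correlation loss for SpO₂
  (Eqs.: `L = L_Dice + λ·(MAE + λ_corr·(1 − ρ))`, all weights 1). The
  network and its backpropagation are implemented directly in R on BLAS
  matrix operations.
* **Evaluation** — IOU-based one-to-one event matching (match iff IOU > 0.1),
  precision/recall/F1, IOU-bin distributions, boundary-error statistics, REI
  + AASM grading (normal < 5 ≤ mild < 15 ≤ moderate < 30 ≤ severe), REI MAE
  and Bland–Altman agreement (`match_events()`, `rei_and_grade()`,
  `recording_agreement()`).

## Worked example

Simulate one night of a severe-grade subject, run the pipeline, and score it:

```r
library(radarsomno)

night <- simulate_night("severe", duration = 600, snr_db = 10, seed = 3)
nrow(night$events)        # 5 scripted events
night$spans               # detected time in bed: 29.6 .. 585.6 s

# train a small model on other subjects, then predict this night
nights <- benchmark_cohort(seed = 1)          # 20 subject-nights, 10 dB SNR
report <- run_benchmark(nights, variant = "full", seed = 1)

report$event$f1           # 0.909 (10 tp, 2 fp, 0 fn on 5 held-out nights)
report$recording$rei_mae  # 2.67  events/hour
report$recording$accuracy # 1.00  severity-grading accuracy
report$spo2$mae_pct       # 2.50  % mean absolute SpO2 error
```

`report$per_night` holds per-recording predicted events, and
`report$recording$confusion` the 4×4 severity confusion matrix. The numbers
above are what the code printed for seed 1 on the standard synthetic
benchmark; they are recomputed from scratch by the acceptance script below.

A YAML-driven end-to-end run (simulate → extract → occupancy → train →
predict → evaluate) is available as `run_pipeline("config.yaml")`, and a thin
command-line wrapper lives at `inst/cli/radarsomno.R`
(`Rscript radarsomno.R simulate|evaluate|pipeline ...`).

## Scope

The clinical dataset behind the method is private; this package validates the
complete method on physically structured synthetic data instead. See
`vignettes/radarsomno-methods.Rmd` for the models, the design choices and
their rationale, and exactly what the synthetic benchmark does and does not
demonstrate.
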