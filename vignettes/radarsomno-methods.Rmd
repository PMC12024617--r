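---
title: "Contactless event-level sleep apnea detection from FMCW radar: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contactless event-level sleep apnea detection from FMCW radar: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`radarsomno` implements a complete pipeline for detecting apnea and hypopnea
events — at the level of individual events, with start and end times — from a
frequency-modulated continuous-wave (FMCW) radar placed at the bedside. The
pipeline has five stages:

1. **Synthesis** (`scene_script()`, `synthesize_if_signal()`,
   `simulate_night()`): a multipoint-scattering simulator generates the radar
   intermediate-frequency (IF) signal of a breathing body, with scripted
   apnea/hypopnea events, a physiologically lagged SpO2 trace, and bed
   entry/exit scenarios.
2. **Signal processing** (`build_range_time_matrix()`,
   `extract_resp_channels()`): per-chirp range FFT, phase unwrapping,
   high-pass filtering, respiratory channel selection, and 50 Hz to 10 Hz
   decimation.
3. **Occupancy detection** (`calibrate_zones()`, `segment_recording()`): a
   debounced six-state machine over three calibrated range zones gates all
   downstream analysis on the Lie-in-Bed state.
4. **Segmentation** (`build_model()`, `train_segmenter()`,
   `predict_recording()`): a multitask 1D U-Net with squeeze-and-excitation
   (SE) blocks and a multihead self-attention (MHSA) bottleneck emits
   per-sample event probability and scaled SpO2.
5. **Evaluation** (`clean_events()`, `match_events()`, `rei_and_grade()`,
   `recording_agreement()`): interval-IOU event matching, precision/recall/F1,
   the respiratory event index (REI), AASM severity grading, and Bland-Altman
   agreement.

# The radar model

## Chirps and the IF signal

The radar transmits chirps whose frequency rises linearly from `f0` (60 GHz)
at slope `S` (65 MHz/us). Mixing the echo with the transmit signal yields, for
a body modelled as N scattering points at distances `d_n(t)`, an IF signal
that is the coherent sum over scatterers of tones with beat frequency
`2 S d_n / c` and phase `4 pi d_n / lambda`. Breathing modulates `d_n(t) =
d_{n,0} + b_n(t)`; scatterers are treated as frozen within one chirp
(microseconds versus seconds of respiratory motion).

Two consequences of the *multipoint* model matter here. First, body energy is
spread over several adjacent range bins, so several bins carry respiratory
information. Second, the coherent sum produces amplitude modulation through
constructive/destructive interference — per-point breathing phase offsets
(`breath_phase`) let the simulator reproduce this, including the paradoxical
chest/abdomen motion seen in obstructive events.

With the default configuration the derived constants are: effective bandwidth
`S * n_adc / fs_adc = 3.328 GHz`, range bin `c / (2B) = 4.51 cm`, wavelength
`5 mm`. The speed of light is taken as `3e8 m/s`; the conventional rounded
constants (4.51 cm bins, hence a 22.55 cm five-bin mid layer) follow from
this rounding.

## Phase demodulation and the effective wavelength

A 1 mm chest displacement at a 5 mm wavelength moves the echo phase by
`4 pi / 5 ~ 2.51 rad` — sub-millimetre sensitivity. One subtlety: the phase of
a range-FFT bin tracks the IF signal at the *centre* of the sampled chirp,
where the instantaneous carrier is `f0 + S (n_adc - 1) / (2 fs_adc)` (about
61.66 GHz here, 2.7 % above `f0`). Displacement demodulation is therefore
exact at `center_wavelength()`, not at `wavelength()`; at a 4 mm breathing
amplitude the difference is ~0.29 rad of systematic deviation, and the
simulator's unwrapped phase matches `4 pi d(t) / center_wavelength` to better
than 0.005 rad in the noiseless case. The package tests pin this identity.

The ADC is modelled as real-valued (I-only) sampling, so the range FFT keeps
the one-sided spectrum (bins `0 .. n_adc/2 - 1`) and IF noise is real
Gaussian. A Hann window controls leakage between adjacent bins, whose phases
are read independently.

## Respiratory channels

Within the calibrated bed and mid layers, candidate bins are ranked by the
respiratory-band (0.1-0.7 Hz) spectral energy of their **complex** bin
signal. Ranking on the unwrapped phase itself would fail: the phase of a
noise-only bin is a random walk whose low-frequency spectral energy exceeds
that of a genuine breathing bin; the complex signal's band energy instead
scales with reflected power times modulation depth and is near zero for
noise. Each selected bin contributes its unwrapped phase, high-pass filtered
by a third-order Butterworth at 0.1 Hz (applied forward-backward, so the
effective magnitude is sixth-order and event boundaries are not phase
shifted), decimated 5:1 to 10 Hz behind a 4 Hz anti-alias low-pass, and
z-scored. The default is `nr = 12` phase channels; amplitude channels are
available (`include_amplitude = TRUE`) but off by default. Because a body
occupies only a few bins, some of the 12 channels are inevitably noise on any
given night — this mirrors real recordings, and channel re-weighting is
exactly what the model's SE blocks are for.

# Bed occupancy

After calibration (strongest mean-energy bin while the subject lies still),
the range axis is split into a nine-bin bed layer (~40 cm), a five-bin mid
layer above it (~22.55 cm, a false-positive buffer), and a top layer of all
remaining bins. Mean zone amplitudes are computed over ten-chirp groups, so
decision frames arrive at 5 Hz and the 15-frame debounce corresponds to 3 s —
the only reading that reconciles the 15-frame debounce with its 3 s duration at a 50 Hz chirp rate.

The six states are NoBody, NearBed, ToBed, LieInBed, FromBed, BadSignal. The
enumerated transitions are implemented exactly (including the perhaps
surprising NearBed entry condition `Pbed >= th_upper`); the FromBed and
BadSignal transition tables are not fully enumerated by the reference design
and are completed symmetrically: FromBed
returns to LieInBed if lie conditions resume before its 15-frame debounce
completes, then routes to NearBed (high bed power) or BadSignal; BadSignal
recovers to ToBed when ToBed entry conditions hold and decays to NoBody after
15 quiet frames. Thresholds are never published; defaults are derived from an
empty-room noise floor (+3, +6, +9 dB for `th_lower`, `th_bed`, `th_upper`),
all overridable. Reachability of every state and the debounce guarantees are
covered by an exhaustive sweep test over threshold-relative power classes.

# The segmentation model

## Architecture

Input is a window `X` of `N = 2048` samples (204.8 s at 10 Hz) by `Nr`
channels. The encoder applies four Convolution(k=3)-BatchNorm-ReLU-SE blocks,
halving time via max pooling after each, with channel widths
`base_channels * (1, 2, 4, 8)`. The bottleneck operates on `N/16 = 128`
tokens: fixed sinusoidal positional encoding is added, then one residual
multihead self-attention layer (4 heads) provides global temporal context —
its job is to compare every time point against the night's normal-breathing
reference. Twin decoders (events; SpO2) mirror the encoder with nearest
upsampling, skip concatenation from the matching encoder stage, and the same
block structure; each head is a kernel-1 convolution with a sigmoid. The
event head's sigmoid is an inference from the loss (soft Dice needs outputs
in [0, 1]); the SpO2 head's sigmoid is as specified. Convolutions use
edge-replicating padding so that a time-constant input yields a time-constant
output and the positional encoding is the only deliberate breaker of
temporal symmetry (pinned by a test).

Ablation variants toggle the attention components: `no_se`, `no_mhsa`
(convolutional bottleneck), `plain` (both off), and `no_spo2_branch`
(single-task).

Because no deep-learning framework is available in R, the network, its
backward pass, and Adam are implemented directly on BLAS matrix operations;
analytic gradients for every layer are verified against central finite
differences in the test suite (tolerance 1e-4 relative).

## Losses

SpO2 labels are scaled by the lower-bound-truncated map `max(y - 80, 0)/20`
(predictions are inverse-mapped to percent). The event loss is soft Dice with
smoothing `eps = 1e-4`; the SpO2 loss is MAE plus `lambda_corr * (1 -
Pearson)`, with the correlation defined as 0 when either side has zero
variance so a mean-collapsed prediction pays the full correlation penalty
rather than passing silently. The total loss is the sum with all weights 1.

One open choice is whether Dice is computed per window and averaged, or over
the whole batch. We compute it **over the batch**: per-window Dice gives an
event-free window a vanishing gradient (`~eps / (sum p + eps)^2`), so nothing
pushes predictions down on event-free subjects, and in development this
produced wall-to-wall false positives on healthy held-out nights. Batch-level
Dice lets empty windows enter the shared denominator and restores that
pressure; the same fix is why the per-window zero-variance correlation rule
above must not be masked.

## Training and inference

Documented defaults follow the reference configuration (batch 32, Adam,
learning rate 1e-5); the desk-scale benchmark uses `base_channels = 4`,
30 epochs, and learning rate 3e-3, which converges on the synthetic cohort
within minutes on one CPU. Training windows are cut at a 30 s step, reduced
to 15 s after any window containing an event (adaptive sampling against class
imbalance; training role only). Inference slides windows at a fixed 30 s step
inside each Lie-in-Bed span, adds one final window aligned to the span end so
the tail is covered, and averages overlapping probabilities; spans shorter
than one window are reflect-padded on the left and cropped. Predicted
probabilities are binarized at 0.5, sub-1 s gaps merged, then events shorter
than 6 s removed — in that order, which the tests pin (two 5 s runs separated
by 0.5 s survive as one 10.5 s event; the reverse order would delete them).

# Synthetic data: what it does and does not emulate

The generator reproduces the study conditions structurally: multipoint
scatterer geometry with per-point gains and phase jitter, quasi-sinusoidal
breathing (12-18 breaths/min, 3-5 mm displacement, optional second harmonic)
with raised-cosine amplitude tapers of ~1.5 s at event edges (no step
discontinuities), hypopnea as a remaining-amplitude fraction `< 0.7`
("airflow reduction exceeding 30 %"), SpO2 desaturation lagged 5-20 s with
depth `1.5-2.5 % per extra 10 s` of event duration, a floor of 80 %, linear
resaturation at 0.5 %/s (a choice; no recovery model is published), additive
Gaussian IF noise at a configurable SNR, and scripted bed entry/exit.

It does **not** emulate: motion artifacts and position changes (including the
body-movement arousal signature at real event ends), heartbeat micro-motion,
multipath clutter, antenna patterns, multi-person scenes, central versus
obstructive event morphology, or annotation noise. Passing the synthetic
recovery benchmark therefore demonstrates that the pipeline is implemented
correctly and can learn the amplitude-suppression signature of events at
realistic SNR — not that it reaches clinical performance on real patients.

## The benchmark and its scale

`benchmark_cohort()` simulates 20 ten-minute nights at 10 dB IF SNR with
events of 15-60 s separated by at least 20 s, five subjects in each AASM
grade (normal/mild/moderate/severe) so that recording-level metrics exercise
every grade; event counts are drawn from each grade's realizable range so the
ground-truth REI matches the scripted severity. `run_benchmark()` holds out
one stratified fold (5 subjects), trains on the remaining 15, and evaluates
on the held-out nights; subjects never cross the split. Night length and
model size are deliberate desk-scale choices: ten-minute nights make REI
coarse (one event changes REI by ~6.4/h), which is why recording-level
agreement is reported but only event-level recovery is asserted. The default
cohort mix of `cohort_spec()` (17/13/3/2 over 35) mirrors a screening-clinic
population for users who want the larger study layout.

# Numerical choices and degenerate inputs

* Sample `i` (1-based) covers the half-open interval `[(i-1)/fs, i/fs)`; all
  intervals are half-open `[start, end)` in seconds.
* IOU matching is one-to-one greedy by descending IOU, ties broken by earlier
  truth start; matches require IOU strictly greater than 0.1. An exhaustive
  assignment oracle over small instances confirms greedy optimality there.
* The IOU distribution bins are `[0,0.3), [0.3,0.6), [0.6,0.8), [0.8,1]` over
  matched events; unmatched truth events can optionally be counted in the
  lowest bin.
* Grading cutoffs are lower-bound inclusive: normal `[0,5)`, mild `[5,15)`,
  moderate `[15,30)`, severe `>= 30`; grading metrics are macro-averaged and
  the full confusion matrix is returned so any other convention can be
  recomputed.
* Zero-denominator precision/recall/F1 are defined as 0 with a warning; an
  empty IOU population yields zeros with a warning; z-scores use a standard
  deviation floor of 1e-6.
* Ties in zone calibration pick the nearest (lowest) bin with a warning.
* One seed drives everything: scene scripts, cohort assembly, splits, weight
  initialization, and shuffling; per-night seeds are derived arithmetically
  from the master seed, and all simulator entry points restore the caller's
  RNG state.

# Known limitations

* The network is CPU-bound R; it is sized for methodological validation, not
  for training on hundreds of clinical nights.
* Only generic "abnormal" events are produced and scored; subtype scoring
  (obstructive/central/hypopnea) is out of scope.
* REI, not AHI, is computed — time in bed is the denominator, as sleep staging
  is unavailable; REI can understate severity relative to AHI.
* The FromBed/BadSignal transition completion and all threshold defaults are
  documented choices, not published facts.
* Artifacts are exchanged as R objects/CSV/JSON; no HDF5 container support.
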