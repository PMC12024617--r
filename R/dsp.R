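# Radar signal processing: range FFT, phase unwrapping, Butterworth filtering,
# respiratory-channel extraction and 10 Hz downsampling.

#' Build the range-time matrix
#'
#' Applies a per-chirp windowed FFT so each column becomes the range profile of
#' one chirp and each row tracks one range bin over slow time. Real (I-only)
#' ADC sampling is assumed, so only the one-sided spectrum
#' (bins `0 .. n_adc/2 - 1`) is kept.
#'
#' @param if_samples Real matrix `[n_adc x n_chirps]` of IF samples.
#' @param cfg A [chirp_config()].
#' @param window FFT window, `"hann"` (default, controls sidelobe leakage into
#'   adjacent bins) or `"rect"`.
#' @return An object of class `range_time_matrix`: list with complex `values`
#'   `[n_bins x n_frames]`, `bin_size` (m), `frame_rate` (Hz), `bin0_range`
#'   (m; 0-based bin indexing, row j holds bin j-1).
#' @export
build_range_time_matrix <- function(if_samples, cfg, window = c("hann", "rect")) {
  window <- match.arg(window)
  if (!is.matrix(if_samples) || nrow(if_samples) != cfg$n_adc) {
    stop_invalid("if_samples must be a [n_adc x n_chirps] matrix")
  }
  w <- if (window == "hann") {
    0.5 * (1 - cos(2 * pi * (seq_len(cfg$n_adc) - 1) / cfg$n_adc))
  } else {
    rep(1, cfg$n_adc)
  }
  spec <- stats::mvfft(if_samples * w)
  n_keep <- cfg$n_adc %/% 2
  rtm <- list(values = spec[seq_len(n_keep), , drop = FALSE],
              bin_size = range_bin_size(cfg),
              frame_rate = cfg$chirp_rate,
              bin0_range = 0)
  class(rtm) <- "range_time_matrix"
  rtm
}

#' Unwrap a phase sequence
#'
#' Restores a continuous phase signal by adding or subtracting multiples of
#' 2*pi wherever a successive difference jumps outside `(-pi, pi]`.
#'
#' @param wrapped Numeric phase sequence in radians.
#' @return Unwrapped sequence; successive differences all lie in `(-pi, pi]`
#'   and the output is congruent to the input modulo 2*pi.
#' @export
unwrap_phase <- function(wrapped) {
  if (any(!is.finite(wrapped))) stop_invalid("phase input must be finite")
  if (length(wrapped) < 2) return(wrapped)
  d <- diff(wrapped)
  # map each difference into (-pi, pi]
  dmod <- d - 2 * pi * ceiling((d - pi) / (2 * pi))
  wrapped[1] + c(0, cumsum(dmod))
}

#' Design the third-order breathing high-pass filter
#'
#' Butterworth high-pass, cutoff 0.1 Hz: removes DC and baseline wander from
#' unwrapped phase while passing the respiratory band (>0.1 Hz).
#'
#' @param fs Sampling rate, Hz.
#' @param cutoff Cutoff frequency, Hz.
#' @param order Filter order.
#' @return A `signal::butter` filter object (`Arma` coefficients).
#' @export
butter_highpass <- function(fs, cutoff = 0.1, order = 3) {
  if (fs <= 4 * cutoff) stop_invalid("fs too low for the requested cutoff")
  signal::butter(order, cutoff / (fs / 2), type = "high")
}

#' Single-pass magnitude response of a digital filter, in dB
#'
#' @param filt A filter object with `$b`, `$a` coefficients.
#' @param f Frequencies of interest, Hz.
#' @param fs Sampling rate, Hz.
#' @return Gain in dB at each frequency.
#' @export
filter_response_db <- function(filt, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  num <- vapply(z, function(zz) sum(filt$b * zz^(seq_along(filt$b) - 1)), complex(1))
  den <- vapply(z, function(zz) sum(filt$a * zz^(seq_along(filt$a) - 1)), complex(1))
  20 * log10(Mod(num / den))
}

#' High-pass filter a breathing trace
#'
#' Applies the third-order 0.1 Hz Butterworth high-pass forward-backward
#' (zero phase, so event boundaries are not shifted; the effective magnitude
#' response is therefore sixth order).
#'
#' @param x Numeric trace.
#' @param fs Sampling rate, Hz.
#' @param cutoff Cutoff, Hz.
#' @param order Single-pass order.
#' @return Filtered trace of the same length.
#' @export
highpass_breathing <- function(x, fs, cutoff = 0.1, order = 3) {
  filt <- butter_highpass(fs, cutoff, order)
  as.numeric(signal::filtfilt(filt, x))
}

# spectral energy of x in [f_lo, f_hi] Hz; for complex input the mirrored
# negative-frequency band is included so real and complex traces rank alike
band_energy <- function(x, fs, f_lo = 0.1, f_hi = 0.7) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  keep <- (f >= f_lo & f <= f_hi) | (f >= fs - f_hi & f <= fs - f_lo)
  sum(sp[keep])
}

# anti-alias low-pass then pick every q-th sample
decimate_trace <- function(x, q, fs, cutoff = 4) {
  filt <- signal::butter(4, cutoff / (fs / 2), type = "low")
  y <- as.numeric(signal::filtfilt(filt, x))
  y[seq(1, length(y), by = q)]
}

#' Extract multichannel respiratory waveforms from a range-time matrix
#'
#' Candidate bed-layer bins are ranked by the respiratory-band (0.1-0.7 Hz)
#' spectral energy of their complex bin signal, which captures both phasic and
#' amplitudinal breathing modulation while staying near zero for noise-only
#' bins (an unwrapped noise phase is a random walk whose low-frequency energy
#' would otherwise swamp the ranking). The top `nr` bins become channels,
#' each emitting its unwrapped, high-pass-filtered phase. Each channel is decimated to `fs_out` (anti-alias
#' low-pass at 4 Hz, 5:1 for a 50 Hz frame rate) and z-scored.
#'
#' @param rtm A `range_time_matrix`.
#' @param zone Optional [zone_layout()]; candidate bins default to the bed
#'   layer plus the adjacent mid layer (the chest wall sits at the bed/mid
#'   boundary), else all bins.
#' @param nr Number of respiratory channels (12 by default).
#' @param fs_out Output rate, Hz.
#' @param include_amplitude If TRUE, also emit `|value|` amplitude channels for
#'   the selected bins (doubling the channel count).
#' @return An object of class `resp_channels`: list with real `values`
#'   `[n_samples x n_channels]`, `fs`, `channel_bins` (0-based source bin per
#'   channel), `channel_kind` (`"phase"`/`"amplitude"`), and `band_energy`
#'   (the ranking scores of the selected bins).
#' @export
extract_resp_channels <- function(rtm, zone = NULL, nr = 12L, fs_out = 10,
                                  include_amplitude = FALSE) {
  vals <- rtm$values
  cand <- if (!is.null(zone)) c(zone$bed_bins, zone$mid_bins) + 1L else seq_len(nrow(vals))
  cand <- cand[cand >= 1 & cand <= nrow(vals)]
  if (nr > length(cand)) {
    stop_invalid("nr exceeds the number of available bed-layer bins")
  }
  fs_in <- rtm$frame_rate
  q <- round(fs_in / fs_out)
  if (abs(fs_in / fs_out - q) > 1e-9) {
    stop_invalid("frame_rate must be an integer multiple of fs_out")
  }
  scores <- vapply(cand, function(j) band_energy(vals[j, ], fs_in), numeric(1))
  pick <- order(scores, decreasing = TRUE)[seq_len(nr)]
  zscore <- function(x) (x - mean(x)) / max(stats::sd(x), 1e-6)
  ch <- lapply(pick, function(i) {
    p <- highpass_breathing(unwrap_phase(Arg(vals[cand[i], ])), fs_in)
    zscore(decimate_trace(p, q, fs_in))
  })
  kinds <- rep("phase", nr)
  bins <- cand[pick] - 1L
  if (include_amplitude) {
    amp <- lapply(pick, function(i) {
      a <- highpass_breathing(Mod(vals[cand[i], ]), fs_in)
      zscore(decimate_trace(a, q, fs_in))
    })
    ch <- c(ch, amp)
    kinds <- c(kinds, rep("amplitude", nr))
    bins <- c(bins, bins)
  }
  out <- list(values = do.call(cbind, ch), fs = fs_out,
              channel_bins = bins, channel_kind = kinds,
              band_energy = scores[pick])
  class(out) <- "resp_channels"
  out
}
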