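# Radar chirp configuration and the analytic constants derived from it.

#' FMCW chirp configuration
#'
#' Parameters of the linearly swept ("chirped") transmit waveform and the ADC
#' that samples the mixed intermediate-frequency (IF) signal. Defaults follow a
#' 60 GHz millimetre-wave sleep-monitoring configuration: 65 MHz/us slope,
#' 5 MHz ADC rate, 256 samples per chirp, 50 chirps per second.
#'
#' @param f0 Start frequency in Hz.
#' @param slope Chirp slope S in Hz/s.
#' @param fs_adc ADC sample rate in Hz.
#' @param n_adc ADC samples recorded per chirp.
#' @param chirp_rate Chirps per second (the slow-time frame rate), Hz.
#' @param tc Chirp duration in s; must cover the ADC acquisition window.
#'   Defaults to `n_adc / fs_adc`.
#' @param tx_amplitude Dimensionless transmit amplitude.
#' @return An object of class `chirp_config`.
#' @examples
#' cfg <- chirp_config()
#' effective_bandwidth(cfg) / 1e9   # ~3.3 GHz
#' range_bin_size(cfg) * 100        # ~4.51 cm
#' @export
chirp_config <- function(f0 = 60e9, slope = 65e6 / 1e-6, fs_adc = 5e6,
                         n_adc = 256L, chirp_rate = 50, tc = n_adc / fs_adc,
                         tx_amplitude = 1) {
  if (f0 <= 0 || slope <= 0 || fs_adc <= 0 || n_adc <= 0 || chirp_rate <= 0) {
    stop_invalid("all chirp parameters must be positive")
  }
  if (tc < n_adc / fs_adc) {
    stop_invalid("chirp duration tc shorter than the ADC acquisition window")
  }
  cfg <- list(f0 = f0, slope = slope, fs_adc = fs_adc, n_adc = as.integer(n_adc),
              chirp_rate = chirp_rate, tc = tc, tx_amplitude = tx_amplitude)
  class(cfg) <- "chirp_config"
  cfg
}

#' Effective sweep bandwidth
#'
#' The bandwidth actually traversed while the ADC records:
#' `B_eff = S * n_adc / fs_adc`.
#'
#' @param cfg A [chirp_config()].
#' @return Bandwidth in Hz.
#' @export
effective_bandwidth <- function(cfg) {
  cfg$slope * (cfg$n_adc / cfg$fs_adc)
}

#' Range-bin size (range resolution)
#'
#' `delta_d = c / (2 B_eff)` with c = 3e8 m/s.
#'
#' @param cfg A [chirp_config()].
#' @return Bin size in metres.
#' @export
range_bin_size <- function(cfg) {
  SPEED_OF_LIGHT / (2 * effective_bandwidth(cfg))
}

#' Carrier wavelength
#'
#' @param cfg A [chirp_config()].
#' @return Wavelength `c / f0` in metres.
#' @export
wavelength <- function(cfg) {
  SPEED_OF_LIGHT / cfg$f0
}

#' Wavelength at the sampled-sweep centre frequency
#'
#' The phase of a range-FFT bin tracks the IF signal at the centre of the
#' sampled chirp, where the instantaneous carrier is
#' `f0 + S (n_adc - 1) / (2 fs_adc)`. Displacement demodulation
#' (`phase = 4 pi d / lambda`) is exact at this wavelength rather than at the
#' start-frequency wavelength.
#'
#' @param cfg A [chirp_config()].
#' @return Wavelength in metres.
#' @export
center_wavelength <- function(cfg) {
  SPEED_OF_LIGHT / (cfg$f0 + cfg$slope * (cfg$n_adc - 1) / (2 * cfg$fs_adc))
}

#' Maximum unambiguous scatterer distance
#'
#' A reflector at distance d delays the echo by `2 d / c`; that delay must fit
#' inside the chirp, so `d <= c * tc / 2`.
#'
#' @param cfg A [chirp_config()].
#' @return Distance in metres.
#' @export
max_unambiguous_range <- function(cfg) {
  SPEED_OF_LIGHT * cfg$tc / 2
}

#' Beat-frequency range bin of a static reflector
#'
#' A reflector at distance d produces an IF tone at `f_b = 2 S d / c`; after an
#' `n_adc`-point FFT it lands in bin `round(f_b * n_adc / fs_adc)` (0-based).
#'
#' @param d Distance in metres.
#' @param cfg A [chirp_config()].
#' @return 0-based range-bin index.
#' @export
range_to_bin <- function(d, cfg) {
  fb <- 2 * cfg$slope * d / SPEED_OF_LIGHT
  as.integer(round(fb * cfg$n_adc / cfg$fs_adc))
}

#' Distance at the centre of a range bin
#'
#' @param bin 0-based bin index.
#' @param cfg A [chirp_config()].
#' @return Distance in metres.
#' @export
bin_to_range <- function(bin, cfg) {
  bin * range_bin_size(cfg)
}

#' @export
print.chirp_config <- function(x, ...) {
  cat("FMCW chirp configuration\n")
  cat(sprintf("  f0: %.1f GHz  slope: %.1f MHz/us  ADC: %.1f MHz x %d\n",
              x$f0 / 1e9, x$slope / 1e12, x$fs_adc / 1e6, x$n_adc))
  cat(sprintf("  chirp rate: %g Hz  B_eff: %.3f GHz  bin: %.2f cm  lambda: %.2f mm\n",
              x$chirp_rate, effective_bandwidth(x) / 1e9,
              range_bin_size(x) * 100, wavelength(x) * 1000))
  invisible(x)
}
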