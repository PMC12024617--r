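# Synthetic night generator: multipoint scatterer geometry, breathing traces
# with apnea/hypopnea events, lagged SpO2 desaturations, occupancy scenarios,
# and the FMCW IF signals they produce.

#' Respiratory event set
#'
#' A sorted, non-overlapping set of half-open `[start, end)` intervals in
#' seconds. `reduction` is the fraction of baseline breathing amplitude that
#' remains during the event: 0 for apnea (complete airflow cessation), below
#' 0.7 for hypopnea (airflow reduction exceeding 30%).
#'
#' @param start,end Numeric vectors of interval bounds in seconds.
#' @param type Character vector, `"apnea"` or `"hypopnea"` (recycled); or
#'   `"abnormal"` for untyped predictions.
#' @param reduction Remaining amplitude fraction per event; defaults to 0 for
#'   apnea and 0.4 for hypopnea.
#' @return A data.frame of class `event_set` with columns
#'   `start`, `end`, `type`, `reduction`.
#' @export
event_set <- function(start = numeric(), end = numeric(),
                      type = "apnea", reduction = NULL) {
  if (length(start) != length(end)) stop_invalid("start/end length mismatch")
  type <- rep_len(type, length(start))
  if (is.null(reduction)) {
    reduction <- ifelse(type == "hypopnea", 0.4, 0)
  }
  reduction <- rep_len(reduction, length(start))
  ev <- data.frame(start = as.numeric(start), end = as.numeric(end),
                   type = type, reduction = as.numeric(reduction),
                   stringsAsFactors = FALSE)
  if (nrow(ev)) {
    ev <- ev[order(ev$start), , drop = FALSE]
    rownames(ev) <- NULL
    if (any(ev$end <= ev$start)) stop_invalid("event end must exceed start")
    if (any(ev$reduction < 0 | ev$reduction >= 1)) {
      stop_invalid("reduction must lie in [0, 1)")
    }
    if (any(ev$type == "hypopnea" & ev$reduction >= 0.7)) {
      stop_invalid("hypopnea requires airflow reduction exceeding 30% (remaining fraction < 0.7)")
    }
    if (nrow(ev) > 1 && any(ev$start[-1] < ev$end[-nrow(ev)])) {
      stop_invalid("events must be non-overlapping")
    }
  }
  class(ev) <- c("event_set", "data.frame")
  ev
}

#' Multipoint scatterer set
#'
#' The body is modelled as N independent scattering points over the chest and
#' abdomen. Each point has a reflection coefficient `alpha`, a static distance
#' `d0` (m), a gain applied to the shared breathing displacement, and a
#' per-point phase offset (rad) of the breathing oscillation, which lets
#' thoracic and abdominal points move out of phase (paradoxical breathing).
#'
#' @param d0 Static distances, m.
#' @param alpha Reflection coefficients (>= 0).
#' @param breath_gain Per-point scale on the breathing displacement.
#' @param breath_phase Per-point breathing phase offsets, rad.
#' @return A data.frame of class `scatterer_set`.
#' @export
scatterer_set <- function(d0, alpha = 1, breath_gain = 1, breath_phase = 0) {
  n <- length(d0)
  if (n == 0) stop_invalid("at least one scatterer required")
  sc <- data.frame(d0 = as.numeric(d0),
                   alpha = rep_len(as.numeric(alpha), n),
                   breath_gain = rep_len(as.numeric(breath_gain), n),
                   breath_phase = rep_len(as.numeric(breath_phase), n))
  if (any(sc$alpha < 0)) stop_invalid("alpha must be >= 0")
  if (any(sc$d0 <= 0)) stop_invalid("d0 must be > 0")
  class(sc) <- c("scatterer_set", "data.frame")
  sc
}

#' Default body scatterer geometry
#'
#' Eight points spread across three adjacent range bins around the body
#' distance, with jittered breathing gains and phases, so that signal energy is
#' distributed across multiple range bins as observed on real chests.
#'
#' @param center_dist Body centre distance from the radar, m.
#' @param cfg A [chirp_config()] (sets the bin spacing).
#' @param n Number of scatterers.
#' @param seed RNG seed for the jitter.
#' @return A [scatterer_set()].
#' @export
body_scatterers <- function(center_dist = 0.9, cfg = chirp_config(), n = 8L,
                            seed = 0L) {
  with_local_seed(seed, {
    dd <- range_bin_size(cfg)
    d0 <- center_dist + runif(n, -1.5 * dd, 1.5 * dd)
    scatterer_set(d0 = d0,
                  alpha = runif(n, 0.5, 1),
                  breath_gain = runif(n, 0.6, 1),
                  breath_phase = rnorm(n, 0, 0.3))
  })
}

#' SpO2 desaturation model
#'
#' Blood-oxygen desaturation lags respiratory-event onset by 5-20 s; nadir
#' depth grows by 1.5-2.5% per extra 10 s of event duration; resaturation is
#' linear after the lagged event end.
#'
#' @param baseline Resting saturation, %.
#' @param lag Delay from event onset to desaturation onset, s (5-20 typical).
#' @param desat_per_10s Depth increment, % per 10 s of event duration.
#' @param floor Minimum saturation, %.
#' @param resat_rate Recovery slope after the lagged event end, %/s.
#' @return An object of class `spo2_model`.
#' @export
spo2_model <- function(baseline = 97, lag = 10, desat_per_10s = 2,
                       floor = 80, resat_rate = 0.5) {
  if (lag < 0) stop_invalid("lag must be >= 0")
  if (baseline <= floor || baseline > 100) {
    stop_invalid("baseline must lie in (floor, 100]")
  }
  if (resat_rate <= 0) stop_invalid("resat_rate must be > 0")
  m <- list(baseline = baseline, lag = lag, desat_per_10s = desat_per_10s,
            floor = floor, resat_rate = resat_rate)
  class(m) <- "spo2_model"
  m
}

#' Occupancy timeline
#'
#' Ordered, non-overlapping phases covering `[0, duration)`:
#' `empty`, `approach`, `in_bed`, `leaving`.
#'
#' @param phase Character vector of phases.
#' @param start,end Phase bounds in seconds.
#' @return A data.frame of class `occupancy_timeline`.
#' @export
occupancy_timeline <- function(phase, start, end) {
  ok <- c("empty", "approach", "in_bed", "leaving")
  if (!all(phase %in% ok)) stop_invalid("unknown occupancy phase")
  tl <- data.frame(phase = phase, start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  tl <- tl[order(tl$start), , drop = FALSE]
  rownames(tl) <- NULL
  if (any(tl$end <= tl$start)) stop_invalid("phase end must exceed start")
  if (nrow(tl) > 1 && any(tl$start[-1] < tl$end[-nrow(tl)])) {
    stop_invalid("occupancy phases must not overlap")
  }
  class(tl) <- c("occupancy_timeline", "data.frame")
  tl
}

#' Scene script: everything needed to simulate one night
#'
#' @param duration Recording length, s.
#' @param breathing_rate Breaths per minute.
#' @param breathing_amp Peak chest displacement, m.
#' @param harmonic2 Relative amplitude of the second breathing harmonic
#'   (0 disables; small values give the slightly peaked morphology of real
#'   chest motion).
#' @param scatterers A [scatterer_set()]; defaults to [body_scatterers()].
#' @param events An [event_set()] of respiratory events; must lie within
#'   `in_bed` spans.
#' @param occupancy An [occupancy_timeline()]; defaults to `in_bed` for the
#'   whole duration.
#' @param spo2 An [spo2_model()].
#' @param noise_sigma Additive Gaussian noise s.d. on IF samples. Ignored when
#'   `snr_db` is given.
#' @param snr_db If non-NULL, noise_sigma is set at synthesis time so the IF
#'   signal-to-noise ratio equals this value in dB.
#' @param seed Integer seed controlling all randomness for this scene.
#' @return An object of class `scene_script`.
#' @export
scene_script <- function(duration, breathing_rate = 15, breathing_amp = 0.004,
                         harmonic2 = 0.15,
                         scatterers = body_scatterers(),
                         events = event_set(),
                         occupancy = NULL,
                         spo2 = spo2_model(),
                         noise_sigma = 0, snr_db = NULL, seed = 1L) {
  if (duration <= 0) stop_invalid("duration must be positive")
  if (is.null(occupancy)) {
    occupancy <- occupancy_timeline("in_bed", 0, duration)
  }
  in_bed <- occupancy[occupancy$phase == "in_bed", , drop = FALSE]
  if (nrow(events)) {
    covered <- vapply(seq_len(nrow(events)), function(i) {
      any(in_bed$start <= events$start[i] & events$end[i] <= in_bed$end)
    }, logical(1))
    if (!all(covered)) stop_invalid("events must lie within in_bed spans")
  }
  s <- list(duration = duration, breathing_rate = breathing_rate,
            breathing_amp = breathing_amp, harmonic2 = harmonic2,
            scatterers = scatterers, events = events, occupancy = occupancy,
            spo2 = spo2, noise_sigma = noise_sigma, snr_db = snr_db,
            seed = as.integer(seed))
  class(s) <- "scene_script"
  s
}

# raised-cosine amplitude envelope: 1 outside events, `reduction` inside,
# tapered over `taper` seconds at each boundary so onsets are gradual
event_envelope <- function(t, events, taper = 1.5) {
  env <- rep(1, length(t))
  if (!nrow(events)) return(env)
  for (i in seq_len(nrow(events))) {
    s <- events$start[i]; e <- events$end[i]; r <- events$reduction[i]
    tp <- min(taper, (e - s) / 2)
    inside <- t >= s & t < e
    f <- rep(1, sum(inside)); ti <- t[inside]
    ramp_in <- ti < s + tp
    f[ramp_in] <- 1 + (r - 1) * 0.5 * (1 - cos(pi * (ti[ramp_in] - s) / tp))
    ramp_out <- ti >= e - tp
    f[ramp_out] <- 1 + (r - 1) * 0.5 * (1 - cos(pi * (e - ti[ramp_out]) / tp))
    f[!ramp_in & !ramp_out] <- r
    env[inside] <- f
  }
  env
}

#' Generate a breathing displacement trace
#'
#' Quasi-sinusoidal chest displacement at the scripted breathing rate.
#' Within each respiratory event the oscillation amplitude is multiplied by
#' the event's remaining fraction, with a raised-cosine taper (~1.5 s) at the
#' boundaries.
#'
#' @param script A [scene_script()].
#' @param fs Sampling rate, Hz; must exceed twice the breathing frequency.
#' @param phase Phase offset of the oscillation, rad.
#' @return Numeric displacement trace in metres, length `duration * fs`.
#' @export
generate_breathing_trace <- function(script, fs, phase = 0) {
  if (script$duration <= 0 || fs <= 0) stop_invalid("duration and fs must be positive")
  f <- script$breathing_rate / 60
  if (fs <= 2 * f) stop_invalid("fs must exceed twice the breathing frequency")
  n <- round(script$duration * fs)
  t <- (seq_len(n) - 1) / fs
  carrier <- sin(2 * pi * f * t + phase) +
    script$harmonic2 * sin(4 * pi * f * t + 2 * phase)
  script$breathing_amp * event_envelope(t, script$events) * carrier
}

#' Generate a lagged SpO2 trace
#'
#' The trace sits at baseline away from events. For an event of duration L a
#' desaturation ramp begins `lag` seconds after event onset, reaches a nadir of
#' `baseline - desat_per_10s * L / 10` (clipped at `floor`) at `end + lag`,
#' then recovers linearly at `resat_rate` %/s. Overlapping profiles combine by
#' pointwise maximum drop.
#'
#' @param events An [event_set()] (sorted, non-overlapping).
#' @param model An [spo2_model()].
#' @param duration Trace length, s.
#' @param fs Sampling rate, Hz.
#' @return Numeric SpO2 trace in percent.
#' @export
generate_spo2_trace <- function(events, model, duration, fs) {
  if (model$lag < 0) stop_invalid("lag must be >= 0")
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  drop <- rep(0, n)
  for (i in seq_len(nrow(events))) {
    s <- events$start[i]; e <- events$end[i]
    L <- e - s
    depth <- min(model$desat_per_10s * L / 10, model$baseline - model$floor)
    t1 <- s + model$lag; t2 <- e + model$lag
    prof <- rep(0, n)
    ramp <- t >= t1 & t < t2
    prof[ramp] <- depth * (t[ramp] - t1) / (t2 - t1)
    rec <- t >= t2
    prof[rec] <- pmax(depth - model$resat_rate * (t[rec] - t2), 0)
    drop <- pmax(drop, prof)
  }
  pmax(model$baseline - drop, model$floor)
}

# IF samples of one scene chunk, real-valued (I-only ADC): for each chirp m at
# slow time t_m and scatterer n at distance d_n(t_m),
#   s[k, m] = sum_n alpha_n A_T cos(2 pi (2 S d_n / c) t_k + 4 pi d_n / lambda)
if_from_distances <- function(dists, alphas, cfg) {
  # dists: [n_chirps x n_scatterers]
  n_chirps <- nrow(dists)
  tk <- (seq_len(cfg$n_adc) - 1) / cfg$fs_adc
  out <- matrix(0, cfg$n_adc, n_chirps)
  for (n in seq_len(ncol(dists))) {
    fb <- 2 * cfg$slope * dists[, n] / SPEED_OF_LIGHT            # [M]
    ph <- 4 * pi * cfg$f0 * dists[, n] / SPEED_OF_LIGHT          # [M]
    arg <- outer(2 * pi * tk, fb) + matrix(ph, cfg$n_adc, n_chirps, byrow = TRUE)
    out <- out + alphas[n] * cfg$tx_amplitude * cos(arg)
  }
  out
}

#' Synthesize the FMCW intermediate-frequency signal of a scene
#'
#' Coherent superposition over all scatterers of the beat tones and phase terms
#' induced by their (breathing-modulated) distances; scatterers are treated as
#' frozen within a single chirp. Additive Gaussian noise is applied per the
#' script's `noise_sigma` or `snr_db`.
#'
#' @param script A [scene_script()].
#' @param cfg A [chirp_config()].
#' @return Real matrix `[n_adc x n_chirps]` of IF samples, with attribute
#'   `"noise_sigma"` recording the noise level actually applied.
#' @export
synthesize_if_signal <- function(script, cfg = chirp_config()) {
  sc <- script$scatterers
  if (is.null(sc) || nrow(sc) == 0) stop_invalid("scatterer list is empty")
  if (any(sc$d0 > max_unambiguous_range(cfg))) {
    stop_invalid("scatterer beyond the unambiguous range of the chirp")
  }
  n_chirps <- round(script$duration * cfg$chirp_rate)
  with_local_seed(script$seed, {
    dists <- matrix(0, n_chirps, nrow(sc))
    for (n in seq_len(nrow(sc))) {
      b <- generate_breathing_trace(script, cfg$chirp_rate,
                                    phase = sc$breath_phase[n])
      dists[, n] <- sc$d0[n] + sc$breath_gain[n] * b[seq_len(n_chirps)]
    }
    sig <- if_from_distances(dists, sc$alpha, cfg)
    sigma <- script$noise_sigma
    if (!is.null(script$snr_db)) {
      sigma <- rms(sig) * 10^(-script$snr_db / 20)
    }
    if (sigma > 0) {
      sig <- sig + matrix(rnorm(length(sig), 0, sigma), nrow(sig), ncol(sig))
    }
    attr(sig, "noise_sigma") <- sigma
    sig
  })
}

#' Synthesize a full occupancy scenario
#'
#' Builds the IF signal of a night with bed entry/exit: nothing but noise while
#' `empty`; static reflectors placed above the bed layer while `approach` and
#' `leaving`; the scripted breathing scatterers while `in_bed`. Phase
#' transitions ramp scatterer amplitude over 1 s.
#'
#' @param script A [scene_script()] whose `occupancy` covers `[0, duration)`.
#' @param cfg A [chirp_config()].
#' @param approach_dist Distance of the standing body during approach/leaving,
#'   m; defaults to 0.35 m nearer the radar than the bed centre.
#' @return List with `rtm` (a [build_range_time_matrix()] result),
#'   `if_samples`, and `truth` (the scripted occupancy timeline).
#' @export
generate_occupancy_scenario <- function(script, cfg = chirp_config(),
                                        approach_dist = NULL) {
  tl <- script$occupancy
  if (min(tl$start) > 0 || max(tl$end) < script$duration) {
    stop_invalid("occupancy_timeline must cover [0, duration]")
  }
  sc <- script$scatterers
  if (is.null(approach_dist)) approach_dist <- mean(sc$d0) - 0.35
  n_chirps <- round(script$duration * cfg$chirp_rate)
  tm <- (seq_len(n_chirps) - 1) / cfg$chirp_rate
  ramp_weight <- function(spans) {
    # 0/1 occupancy with 1 s raised-cosine ramps at span edges
    w <- rep(0, n_chirps)
    for (i in seq_len(nrow(spans))) {
      s <- spans$start[i]; e <- spans$end[i]
      inside <- tm >= s & tm < e
      wi <- rep(1, sum(inside)); ti <- tm[inside]
      rin <- ti < s + 1
      wi[rin] <- 0.5 * (1 - cos(pi * (ti[rin] - s)))
      rout <- ti >= e - 1
      wi[rout] <- pmin(wi[rout], 0.5 * (1 - cos(pi * (e - ti[rout]))))
      w[inside] <- pmax(w[inside], wi)
    }
    w
  }
  w_bed <- ramp_weight(tl[tl$phase == "in_bed", , drop = FALSE])
  w_app <- ramp_weight(tl[tl$phase %in% c("approach", "leaving"), , drop = FALSE])

  with_local_seed(script$seed, {
    dists <- matrix(0, n_chirps, nrow(sc))
    for (n in seq_len(nrow(sc))) {
      b <- generate_breathing_trace(script, cfg$chirp_rate,
                                    phase = sc$breath_phase[n])
      dists[, n] <- sc$d0[n] + sc$breath_gain[n] * b[seq_len(n_chirps)]
    }
    sig <- matrix(0, cfg$n_adc, n_chirps)
    # bed-layer breathing reflectors, weighted by in_bed occupancy
    tk <- (seq_len(cfg$n_adc) - 1) / cfg$fs_adc
    for (n in seq_len(nrow(sc))) {
      fb <- 2 * cfg$slope * dists[, n] / SPEED_OF_LIGHT
      ph <- 4 * pi * cfg$f0 * dists[, n] / SPEED_OF_LIGHT
      arg <- outer(2 * pi * tk, fb) + matrix(ph, cfg$n_adc, n_chirps, byrow = TRUE)
      sig <- sig + sweep(sc$alpha[n] * cos(arg), 2, w_bed, `*`)
    }
    # standing-body reflectors in the mid/top layers during approach/leaving
    if (any(w_app > 0)) {
      app_d <- approach_dist + c(-0.02, 0, 0.02)
      for (d in app_d) {
        fb <- 2 * cfg$slope * d / SPEED_OF_LIGHT
        ph <- 4 * pi * cfg$f0 * d / SPEED_OF_LIGHT
        tone <- cos(2 * pi * tk * fb + ph)
        sig <- sig + outer(tone, 0.8 * w_app)
      }
    }
    sigma <- script$noise_sigma
    if (!is.null(script$snr_db)) {
      ref <- rms(sig[, w_bed > 0.99, drop = FALSE])
      sigma <- ref * 10^(-script$snr_db / 20)
    }
    if (sigma > 0) {
      sig <- sig + matrix(rnorm(length(sig), 0, sigma), nrow(sig), ncol(sig))
    }
    attr(sig, "noise_sigma") <- sigma
    list(rtm = build_range_time_matrix(sig, cfg), if_samples = sig, truth = tl)
  })
}
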