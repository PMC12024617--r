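# Bed-occupancy detection: calibrated three-zone range partition, per-zone
# power levels at 5 Hz decision frames, and a debounced six-state machine that
# gates event segmentation on the Lie-in-Bed state.

#' Three-zone range partition
#'
#' The bed layer is nine range bins (about 40 cm at a 4.51 cm bin) centred on
#' the calibrated body bin; the mid layer is the five bins adjacent above it
#' (towards the radar, about 22.55 cm), a buffer against false positives; the
#' top layer is every remaining bin.
#'
#' @param bed_center_bin 0-based central bed bin.
#' @param n_bins Total number of range bins.
#' @return An object of class `zone_layout` with 0-based `bed_bins`,
#'   `mid_bins`, `top_bins`, `bed_center_bin`.
#' @export
zone_layout <- function(bed_center_bin, n_bins) {
  bed <- (bed_center_bin - 4):(bed_center_bin + 4)
  mid <- (bed_center_bin - 9):(bed_center_bin - 5)
  if (min(mid) < 0 || max(bed) > n_bins - 1) {
    stop_invalid("zone layout does not fit within the range bins")
  }
  top <- setdiff(0:(n_bins - 1), c(bed, mid))
  z <- list(bed_center_bin = bed_center_bin, bed_bins = bed,
            mid_bins = mid, top_bins = top, n_bins = as.integer(n_bins))
  class(z) <- "zone_layout"
  z
}

#' Calibrate the zone layout from a still-subject segment
#'
#' Selects the range bin with the strongest mean reflection energy as the bed
#' layer's central reference point.
#'
#' @param rtm A `range_time_matrix` recorded with the subject lying still
#'   (>= 10 s).
#' @return A [zone_layout()].
#' @export
calibrate_zones <- function(rtm) {
  if (is.null(rtm$values) || ncol(rtm$values) == 0) {
    stop_invalid("empty range-time matrix")
  }
  if (ncol(rtm$values) / rtm$frame_rate < 10) {
    stop_invalid("calibration segment must be at least 10 s")
  }
  p <- rowMeans(Mod(rtm$values))
  best <- which(p == max(p))
  if (length(best) > 1) {
    warning("tie in calibration energy; choosing the nearest bin")
    best <- min(best)
  }
  zone_layout(best - 1L, nrow(rtm$values))
}

#' Occupancy thresholds
#'
#' Amplitude thresholds relative to an estimated noise floor:
#' `th_lower` = floor + 3 dB, `th_bed` = floor + 6 dB, `th_upper` = floor +
#' 9 dB by default (all overridable).
#'
#' @param noise_floor Mean zone amplitude of an empty room.
#' @param th_lower,th_bed,th_upper Explicit thresholds (power units of
#'   [zone_powers()]).
#' @return An object of class `occ_thresholds`.
#' @export
occ_thresholds <- function(noise_floor = NULL,
                           th_lower = noise_floor * 10^(3 / 20),
                           th_bed = noise_floor * 10^(6 / 20),
                           th_upper = noise_floor * 10^(9 / 20)) {
  if (!(th_upper > th_lower && th_lower > 0 && th_bed > 0)) {
    stop_invalid("need th_upper > th_lower > 0 and th_bed > 0")
  }
  th <- list(th_lower = th_lower, th_bed = th_bed, th_upper = th_upper)
  class(th) <- "occ_thresholds"
  th
}

#' Per-zone power levels at the decision-frame rate
#'
#' Averages `|value|` over each zone's bins, then over groups of `group`
#' chirps, turning the 50 Hz chirp stream into 5 Hz decision frames (so the
#' 15-frame debounce spans 3 s).
#'
#' @param rtm A `range_time_matrix`.
#' @param layout A [zone_layout()].
#' @param group Chirps averaged per decision frame.
#' @return Matrix `[n_frames x 3]` with columns `Ptop`, `Pmid`, `Pbed` and
#'   attribute `"frame_rate"`.
#' @export
zone_powers <- function(rtm, layout, group = 10L) {
  a <- Mod(rtm$values)
  if (nrow(a) < layout$n_bins) stop_invalid("matrix does not cover the layout")
  zp <- cbind(Ptop = colMeans(a[layout$top_bins + 1L, , drop = FALSE]),
              Pmid = colMeans(a[layout$mid_bins + 1L, , drop = FALSE]),
              Pbed = colMeans(a[layout$bed_bins + 1L, , drop = FALSE]))
  n_grp <- nrow(zp) %/% group
  idx <- rep(seq_len(n_grp), each = group)
  out <- apply(zp[seq_along(idx), , drop = FALSE], 2,
               function(col) tapply(col, idx, mean))
  out <- matrix(out, ncol = 3, dimnames = list(NULL, c("Ptop", "Pmid", "Pbed")))
  attr(out, "frame_rate") <- rtm$frame_rate / group
  out
}

OCC_STATES <- c("NoBody", "NearBed", "ToBed", "LieInBed", "FromBed", "BadSignal")
OCC_DEBOUNCE <- 15L

#' Initial occupancy state
#' @return An `occ_state` list with `value = "NoBody"` and zero debounce count.
#' @export
occ_state_init <- function() {
  s <- list(value = "NoBody", count = 0L)
  class(s) <- "occ_state"
  s
}

# condition helpers
occ_lie_hold <- function(p, th) {
  p["Ptop"] < th$th_lower && p["Pmid"] < th$th_lower && p["Pbed"] >= th$th_bed
}
occ_tobed_cond <- function(p, th) {
  p["Pbed"] >= th$th_bed && p["Ptop"] < th$th_upper
}
occ_badsig_cond <- function(p, th) {
  p["Pbed"] < th$th_bed && p["Ptop"] < th$th_lower && p["Pmid"] < th$th_lower
}

#' Advance the occupancy state machine by one decision frame
#'
#' Transition rules (power comparisons against `th_lower < th_upper` and
#' `th_bed`, with a 15-frame debounce on entering Lie-in-Bed and on leaving
#' via From-Bed):
#' \itemize{
#' \item NoBody: stays while `Pbed < th_upper`; else to NearBed.
#' \item NearBed: to BadSignal when all three zones are quiet
#'   (`Pbed < th_bed`, `Ptop < th_lower`, `Pmid < th_lower`); to ToBed when
#'   `Pbed >= th_bed` and `Ptop < th_upper`; else stays.
#' \item ToBed: counts frames with `Ptop < th_upper` and `Pbed >= th_bed`;
#'   after 15 consecutive qualifying frames enters LieInBed; a non-qualifying
#'   frame resets and falls back to NearBed (or BadSignal when all quiet).
#' \item LieInBed: maintained while `Ptop < th_lower`, `Pmid < th_lower` and
#'   `Pbed >= th_bed`; otherwise to FromBed.
#' \item FromBed: returns to LieInBed if the lie conditions resume before the
#'   15-frame debounce completes; after it completes, to NearBed when
#'   `Pbed >= th_upper`, else to BadSignal.
#' \item BadSignal: to ToBed when the ToBed entry conditions hold; to NoBody
#'   after `Pbed < th_upper` persists 15 frames; else stays.
#' }
#'
#' @param state An `occ_state`.
#' @param powers Named numeric vector `c(Ptop=, Pmid=, Pbed=)`.
#' @param th An [occ_thresholds()].
#' @return The next `occ_state`.
#' @export
occ_step <- function(state, powers, th) {
  p <- powers
  v <- state$value
  cnt <- state$count
  nxt <- switch(
    v,
    NoBody = {
      if (p["Pbed"] >= th$th_upper) list("NearBed", 0L) else list("NoBody", 0L)
    },
    NearBed = {
      if (occ_badsig_cond(p, th)) list("BadSignal", 0L)
      else if (occ_tobed_cond(p, th)) list("ToBed", 1L)
      else list("NearBed", 0L)
    },
    ToBed = {
      if (occ_tobed_cond(p, th)) {
        if (cnt + 1L >= OCC_DEBOUNCE) list("LieInBed", 0L)
        else list("ToBed", cnt + 1L)
      } else if (occ_badsig_cond(p, th)) list("BadSignal", 0L)
      else list("NearBed", 0L)
    },
    LieInBed = {
      if (occ_lie_hold(p, th)) list("LieInBed", 0L) else list("FromBed", 1L)
    },
    FromBed = {
      if (occ_lie_hold(p, th)) list("LieInBed", 0L)
      else if (cnt + 1L >= OCC_DEBOUNCE) {
        if (p["Pbed"] >= th$th_upper) list("NearBed", 0L)
        else list("BadSignal", 0L)
      } else list("FromBed", cnt + 1L)
    },
    BadSignal = {
      if (occ_tobed_cond(p, th)) list("ToBed", 1L)
      else if (p["Pbed"] < th$th_upper) {
        if (cnt + 1L >= OCC_DEBOUNCE) list("NoBody", 0L)
        else list("BadSignal", cnt + 1L)
      } else list("BadSignal", 0L)
    },
    stop_invalid("unknown occupancy state: ", v)
  )
  out <- list(value = nxt[[1]], count = nxt[[2]])
  class(out) <- "occ_state"
  out
}

#' Run the state machine over a power-level sequence
#'
#' @param powers Matrix from [zone_powers()].
#' @param th An [occ_thresholds()].
#' @param init Initial state.
#' @return Character vector of states, one per decision frame.
#' @export
occ_run <- function(powers, th, init = occ_state_init()) {
  st <- init
  out <- character(nrow(powers))
  for (i in seq_len(nrow(powers))) {
    st <- occ_step(st, powers[i, ], th)
    out[i] <- st$value
  }
  out
}

#' Segment a recording into time-in-bed spans
#'
#' Runs the occupancy machine and returns maximal Lie-in-Bed spans; their
#' total duration is the recording's time in bed used by the respiratory
#' event index. Gaps shorter than the 3 s debounce are bridged: re-entering
#' Lie-in-Bed through To-Bed always takes at least 15 frames, so any shorter
#' interruption is a From-Bed excursion that returned — occupancy never
#' actually ended.
#'
#' @param rtm A `range_time_matrix`.
#' @param layout A [zone_layout()].
#' @param th An [occ_thresholds()].
#' @param group Chirps per decision frame.
#' @return data.frame with columns `start`, `end` in seconds.
#' @export
segment_recording <- function(rtm, layout, th, group = 10L) {
  powers <- zone_powers(rtm, layout, group)
  fr <- attr(powers, "frame_rate")
  states <- occ_run(powers, th)
  inbed <- states == "LieInBed"
  if (!any(inbed)) {
    return(data.frame(start = numeric(), end = numeric()))
  }
  r <- rle(inbed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  spans <- data.frame(start = (starts[keep] - 1) / fr, end = ends[keep] / fr)
  merged <- spans[1, , drop = FALSE]
  for (i in seq_len(nrow(spans))[-1]) {
    if (spans$start[i] - merged$end[nrow(merged)] < OCC_DEBOUNCE / fr) {
      merged$end[nrow(merged)] <- spans$end[i]
    } else {
      merged <- rbind(merged, spans[i, ])
    }
  }
  merged
}
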