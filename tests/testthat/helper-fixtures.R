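# Shared fixtures, built in code at test time.

fixture_cfg <- function() chirp_config()

# one static reflector, noiseless
static_scene <- function(d = 0.5, duration = 1, seed = 1) {
  scene_script(duration = duration, breathing_amp = 0,
               scatterers = scatterer_set(d), seed = seed)
}

# one breathing reflector
breather_scene <- function(d = 0.5, duration = 30, rate = 15, amp = 0.004,
                           snr_db = NULL, seed = 1, events = event_set(),
                           harmonic2 = 0) {
  scene_script(duration = duration, breathing_rate = rate,
               breathing_amp = amp, harmonic2 = harmonic2,
               scatterers = scatterer_set(d), events = events,
               snr_db = snr_db, seed = seed)
}

# tiny model configuration used by network unit tests
tiny_model_cfg <- function(variant = "full", pos_encoding = "sinusoidal") {
  segmenter_config(nr = 2L, n = 64L, base_channels = 2L, se_ratio = 2L,
                   n_heads = 2L, variant = variant,
                   pos_encoding = pos_encoding)
}

# brute-force optimal one-to-one event assignment (max matches, then max
# total IOU) for small instances; independent oracle for match_events
oracle_match <- function(pred, truth, iou_min = 0.1) {
  np <- nrow(pred); nt <- nrow(truth)
  if (np == 0 || nt == 0) return(list(tp = 0, total_iou = 0))
  iou <- matrix(0, np, nt)
  for (i in seq_len(np)) {
    for (j in seq_len(nt)) {
      iou[i, j] <- interval_iou(c(pred$start[i], pred$end[i]),
                                c(truth$start[j], truth$end[j]))
    }
  }
  best_tp <- 0; best_iou <- 0
  k <- min(np, nt)
  preds <- seq_len(np)
  # enumerate all injective assignments truth-subset -> pred
  recurse <- function(j, used, tp, tot) {
    if (j > nt) {
      if (tp > best_tp || (tp == best_tp && tot > best_iou)) {
        best_tp <<- tp; best_iou <<- tot
      }
      return(invisible(NULL))
    }
    recurse(j + 1, used, tp, tot)  # truth j unmatched
    for (i in preds[!used]) {
      if (iou[i, j] > iou_min) {
        used[i] <- TRUE
        recurse(j + 1, used, tp + 1, tot + iou[i, j])
        used[i] <- FALSE
      }
    }
  }
  recurse(1, logical(np), 0, 0)
  list(tp = best_tp, total_iou = best_iou)
}

random_event_set <- function(n, horizon = 600) {
  if (n == 0) return(event_set())
  starts <- sort(runif(n, 0, horizon - 30))
  durs <- runif(n, 5, 40)
  # enforce disjointness
  for (i in seq_len(n)[-1]) {
    starts[i] <- max(starts[i], starts[i - 1] + durs[i - 1] + 0.5)
  }
  event_set(starts, starts + durs, "abnormal", reduction = 0)
}

rms <- function(x) sqrt(mean(x^2))
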