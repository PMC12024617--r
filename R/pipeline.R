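# Dataset assembly and end-to-end orchestration: windowing with adaptive
# sampling, subject-wise stratified cross-validation splits, synthetic cohort
# simulation, and the simulate -> extract -> occupancy -> train -> predict ->
# evaluate pipeline.

#' Per-sample event label trace
#'
#' @param events An [event_set()].
#' @param duration Trace length, s.
#' @param fs Sampling rate, Hz.
#' @return 0/1 vector of length `duration * fs` (half-open intervals).
#' @export
label_trace <- function(events, duration, fs) {
  n <- round(duration * fs)
  y <- rep(0, n)
  for (i in seq_len(nrow(events))) {
    a <- time_to_index(events$start[i], fs)
    b <- min(time_to_index(events$end[i], fs) - 1L, n)
    if (b >= a) y[a:b] <- 1
  }
  y
}

#' Cut aligned traces into training/inference windows
#'
#' Slides 204.8 s windows inside the time-in-bed spans. In the training role
#' the step after a window containing any abnormal event drops from 30 s to
#' 15 s (adaptive sampling against class imbalance); the test role always
#' steps 30 s. Partial windows at span edges are dropped. Each window's
#' channels are z-scored per channel.
#'
#' @param channels A `resp_channels` object (or plain matrix at `fs` Hz).
#' @param y_event Per-sample 0/1 event labels, same length.
#' @param y_spo2 Per-sample scaled SpO2 labels (may be NULL).
#' @param spans data.frame of in-bed spans (`start`, `end`, s); default one
#'   span covering everything.
#' @param role `"train"` (adaptive step) or `"test"` (fixed step).
#' @param window_s Window length, s.
#' @param step_s Base step, s.
#' @param adaptive_step_s Step after event-containing training windows, s.
#' @param fs Sampling rate when `channels` is a bare matrix.
#' @return List of window samples (`x`, `y_event`, `y_spo2`, `t_start`).
#' @export
make_windows <- function(channels, y_event, y_spo2 = NULL, spans = NULL,
                         role = c("train", "test"), window_s = 204.8,
                         step_s = 30, adaptive_step_s = 15, fs = 10) {
  role <- match.arg(role)
  x <- if (is.matrix(channels)) channels else channels$values
  if (!is.matrix(channels)) fs <- channels$fs
  if (nrow(x) != length(y_event)) stop_invalid("labels misaligned with channels")
  if (!is.null(y_spo2) && length(y_spo2) != length(y_event)) {
    stop_invalid("SpO2 labels misaligned with event labels")
  }
  if (is.null(spans)) spans <- data.frame(start = 0, end = nrow(x) / fs)
  n <- round(window_s * fs)
  zs <- function(m) {
    out <- vapply(seq_len(ncol(m)), function(j) {
      (m[, j] - mean(m[, j])) / max(stats::sd(m[, j]), 1e-6)
    }, numeric(nrow(m)))
    matrix(out, nrow(m), ncol(m))
  }
  out <- list()
  for (k in seq_len(nrow(spans))) {
    i0 <- time_to_index(spans$start[k], fs)
    i1 <- min(time_to_index(spans$end[k], fs) - 1L, nrow(x))
    pos <- i0
    # the first window may fit the span exactly; stepped windows must leave
    # strictly positive room, so a span of one window length yields exactly
    # one window and window + k steps never sits flush at the span end
    while (if (pos == i0) pos + n - 1L <= i1 else pos + n - 1L < i1) {
      rows <- pos:(pos + n - 1L)
      ye <- y_event[rows]
      out[[length(out) + 1]] <- list(
        x = zs(x[rows, , drop = FALSE]),
        y_event = ye,
        y_spo2 = if (!is.null(y_spo2)) y_spo2[rows],
        t_start = (pos - 1) / fs)
      step <- if (role == "train" && any(ye > 0)) adaptive_step_s else step_s
      pos <- pos + round(step * fs)
    }
  }
  out
}

#' Subject-wise stratified fold assignment
#'
#' Subjects are stratified by severity and dealt round-robin into `k` folds
#' after a seeded shuffle, so folds are subject-disjoint and severity strata
#' differ by at most one subject across folds.
#'
#' @param subjects data.frame with columns `id` and `severity`.
#' @param k Number of folds.
#' @param seed Shuffle seed.
#' @return data.frame `id`, `severity`, `fold`.
#' @export
make_splits <- function(subjects, k = 5L, seed = 1L) {
  if (nrow(subjects) < k) stop_invalid("fewer subjects than folds")
  with_local_seed(seed, {
    out <- NULL
    offset <- 0L
    for (sv in unique(subjects$severity)) {
      ids <- subjects$id[subjects$severity == sv]
      ids <- sample(ids)
      folds <- ((seq_along(ids) - 1L + offset) %% k) + 1L
      offset <- (offset + length(ids)) %% k
      out <- rbind(out, data.frame(id = ids, severity = sv, fold = folds))
    }
    out[order(match(out$id, subjects$id)), , drop = FALSE]
  })
}

#' Synthetic cohort specification
#'
#' @param n_subjects Number of simulated nights (one subject each).
#' @param severity_mix Named proportions over
#'   `c(normal, mild, moderate, severe)`; must sum to 1. The default mirrors
#'   a screening-clinic mix of 17/13/3/2 over 35 subjects.
#' @param night_duration Night length, s.
#' @param snr_db IF-signal signal-to-noise ratio, dB.
#' @param seed Master seed; per-night seeds are derived from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 35L,
                        severity_mix = c(normal = 17, mild = 13,
                                         moderate = 3, severe = 2) / 35,
                        night_duration = 600, snr_db = 10, seed = 1L) {
  if (abs(sum(severity_mix) - 1) > 1e-8) {
    stop_invalid("severity mix proportions must sum to 1")
  }
  sp <- list(n_subjects = as.integer(n_subjects), severity_mix = severity_mix,
             night_duration = night_duration, snr_db = snr_db,
             seed = as.integer(seed))
  class(sp) <- "cohort_spec"
  sp
}

# REI target ranges (events/h) per severity grade
REI_RANGES <- list(normal = c(0, 4), mild = c(5, 14),
                   moderate = c(15, 29), severe = c(30, 45))

# place n_events non-overlapping events of 15-60 s inside [lo, hi] with
# >= 20 s separation (room for distinct SpO2 desaturations)
place_events <- function(n_events, lo, hi, gap = 20) {
  if (n_events == 0) return(event_set())
  span <- hi - lo
  gap_total <- gap * (n_events - 1)
  durs <- stats::runif(n_events, 15, 60)
  if (sum(durs) + gap_total > span) {
    cap <- (span - gap_total) / n_events
    if (cap < 15) {
      stop_invalid("could not place ", n_events, " events in the in-bed span")
    }
    durs <- pmin(durs, cap)
  }
  # spread the remaining slack randomly before each event
  slack <- span - sum(durs) - gap_total
  extras <- diff(c(0, sort(stats::runif(n_events, 0, slack))))
  starts <- numeric(n_events)
  pos <- lo
  for (i in seq_len(n_events)) {
    starts[i] <- pos + extras[i]
    pos <- starts[i] + durs[i] + gap
  }
  types <- sample(c("apnea", "hypopnea"), n_events, replace = TRUE,
                  prob = c(0.7, 0.3))
  event_set(starts, starts + durs, types)
}

#' Simulate one synthetic night end to end
#'
#' Builds the scene (bed entry, in-bed breathing with randomly placed
#' apnea/hypopnea events at the grade's event rate, bed exit), synthesizes the
#' IF signal, constructs the range-time matrix, calibrates zones, runs the
#' occupancy machine, extracts respiratory channels, and assembles aligned
#' label traces.
#'
#' @param severity One of normal/mild/moderate/severe.
#' @param duration Night length, s.
#' @param snr_db IF signal-to-noise ratio, dB.
#' @param seed Night seed.
#' @param cfg A [chirp_config()].
#' @param nr Respiratory channels extracted.
#' @return A `sim_night` list: `channels`, `spans` (detected), `events`
#'   (truth), `y_event`, `y_spo2` (scaled), `spo2_pct`, `grade`, `rei_truth`,
#'   `tib_truth_h`, `script`, `layout`, `thresholds`.
#' @export
simulate_night <- function(severity = "moderate", duration = 600, snr_db = 10,
                           seed = 1L, cfg = chirp_config(), nr = 12L) {
  severity <- match.arg(severity, names(REI_RANGES))
  with_local_seed(seed, {
    bed_start <- 26; bed_end <- duration - 14
    tl <- occupancy_timeline(
      phase = c("empty", "approach", "in_bed", "leaving", "empty"),
      start = c(0, 20, bed_start, bed_end, duration - 8),
      end = c(20, bed_start, bed_end, duration - 8, duration))
    tib_h <- (bed_end - bed_start) / 3600
    # draw an event count whose realized REI (= n / tib) lies inside the
    # grade's range; at short nights the count is the controlling quantity
    rr <- REI_RANGES[[severity]]
    n_min <- ceiling(rr[1] * tib_h)
    n_max <- max(n_min, floor(rr[2] * tib_h))
    n_events <- if (n_max > n_min) sample(n_min:n_max, 1) else n_min
    events <- place_events(n_events, bed_start + 15, bed_end - 15)
    script <- scene_script(
      duration = duration,
      breathing_rate = stats::runif(1, 12, 18),
      breathing_amp = stats::runif(1, 0.003, 0.005),
      scatterers = body_scatterers(stats::runif(1, 0.8, 1.0), cfg,
                                   seed = seed + 1000L),
      events = events, occupancy = tl, snr_db = snr_db,
      seed = seed + 2000L)
    scen <- generate_occupancy_scenario(script, cfg)
    rtm <- scen$rtm
    # calibrate on an early still in-bed segment; noise floor from the
    # leading empty-room segment
    calib_cols <- which(seq_len(ncol(rtm$values)) / rtm$frame_rate > bed_start + 2 &
                          seq_len(ncol(rtm$values)) / rtm$frame_rate <= bed_start + 14)
    calib <- rtm
    calib$values <- rtm$values[, calib_cols, drop = FALSE]
    layout <- calibrate_zones(calib)
    empty_cols <- seq_len(round(18 * rtm$frame_rate))
    nf <- mean(Mod(rtm$values[layout$bed_bins + 1L, empty_cols]))
    th <- occ_thresholds(nf)
    spans <- segment_recording(rtm, layout, th)
    channels <- extract_resp_channels(rtm, layout, nr = nr)
    y_event <- label_trace(events, duration, channels$fs)
    spo2_pct <- generate_spo2_trace(events, script$spo2, duration, channels$fs)
    rei_truth <- nrow(events) / tib_h
    night <- list(channels = channels, spans = spans, events = events,
                  y_event = y_event, y_spo2 = scale_spo2(spo2_pct),
                  spo2_pct = spo2_pct, grade = severity,
                  rei_truth = rei_truth, tib_truth_h = tib_h,
                  script = script, layout = layout, thresholds = th)
    class(night) <- "sim_night"
    night
  })
}

#' Simulate a cohort of synthetic nights
#'
#' @param spec A [cohort_spec()].
#' @param cfg A [chirp_config()].
#' @param verbose Print progress.
#' @return List of `sim_night` objects with a `subjects` attribute
#'   (data.frame `id`, `severity`).
#' @export
simulate_cohort <- function(spec = cohort_spec(), cfg = chirp_config(),
                            verbose = FALSE) {
  counts <- round(spec$severity_mix * spec$n_subjects)
  # fix rounding drift on the largest class
  counts[which.max(counts)] <- counts[which.max(counts)] +
    spec$n_subjects - sum(counts)
  severities <- rep(names(counts), counts)
  nights <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    if (verbose) message("simulating night ", i, " (", severities[i], ")")
    nights[[i]] <- simulate_night(severities[i], spec$night_duration,
                                  spec$snr_db, seed = spec$seed * 1000L + i,
                                  cfg = cfg)
  }
  attr(nights, "subjects") <- data.frame(id = seq_len(spec$n_subjects),
                                         severity = severities)
  nights
}

#' Assemble training windows from a set of nights
#'
#' @param nights List of `sim_night` objects.
#' @param role `"train"` or `"test"` (controls adaptive sampling).
#' @return List of window samples.
#' @export
cohort_windows <- function(nights, role = "train") {
  out <- list()
  for (nt in nights) {
    w <- make_windows(nt$channels, nt$y_event, nt$y_spo2, nt$spans, role = role)
    out <- c(out, w)
  }
  out
}

#' Evaluate a trained model on held-out nights
#'
#' Runs windowed inference over each night's detected in-bed spans, cleans the
#' probability traces into events, pools event matches across nights, and
#' summarises recording-level agreement.
#'
#' @param model A trained `segmenter_model`.
#' @param nights Held-out `sim_night` list.
#' @param threshold Probability binarization threshold.
#' @return List with `event` (pooled tp/fp/fn, precision/recall/f1,
#'   `iou_distribution`, `boundary`), `recording` (a [recording_agreement()]
#'   result), `spo2` (MAE %, Pearson correlation over in-bed samples), and
#'   `per_night` details.
#' @export
evaluate_nights <- function(model, nights, threshold = 0.5) {
  tp <- fp <- fn <- 0
  all_ious <- numeric()
  n_unmatched <- 0
  errs <- NULL
  pred_sum <- list(); true_sum <- list()
  spo2_err <- numeric(); spo2_pred_all <- numeric(); spo2_true_all <- numeric()
  per_night <- list()
  for (i in seq_along(nights)) {
    nt <- nights[[i]]
    pr <- predict_recording(model, nt$channels, nt$spans)
    prob <- ifelse(is.na(pr$event), 0, pr$event)
    pred_ev <- clean_events(prob, pr$fs, threshold)
    m <- match_events(pred_ev, nt$events)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    all_ious <- c(all_ious, m$matches$iou)
    n_unmatched <- n_unmatched + length(m$unmatched_truth)
    if (m$tp > 0) errs <- rbind(errs, boundary_errors(m)$errors)
    tib_pred <- sum(nt$spans$end - nt$spans$start) / 3600
    pred_sum[[i]] <- rei_and_grade(pred_ev, max(tib_pred, 1e-9))
    true_sum[[i]] <- rei_and_grade(nt$events, nt$tib_truth_h)
    if (!is.null(pr$spo2_pct)) {
      ok <- !is.na(pr$spo2_pct)
      spo2_err <- c(spo2_err, abs(pr$spo2_pct[ok] - nt$spo2_pct[ok]))
      spo2_pred_all <- c(spo2_pred_all, pr$spo2_pct[ok])
      spo2_true_all <- c(spo2_true_all, nt$spo2_pct[ok])
    }
    per_night[[i]] <- list(pred_events = pred_ev, match = m,
                           rei_pred = pred_sum[[i]]$rei,
                           rei_truth = true_sum[[i]]$rei)
  }
  pr3 <- suppressWarnings(prf1(tp, fp, fn))
  fake_match <- list(matches = data.frame(iou = all_ious),
                     unmatched_truth = seq_len(n_unmatched))
  dist <- suppressWarnings(iou_distribution(fake_match))
  spo2 <- NULL
  if (length(spo2_err)) {
    corr <- if (stats::sd(spo2_pred_all) > 0 && stats::sd(spo2_true_all) > 0) {
      stats::cor(spo2_pred_all, spo2_true_all)
    } else 0
    spo2 <- list(mae_pct = mean(spo2_err), corr = corr)
  }
  list(event = list(tp = tp, fp = fp, fn = fn,
                    precision = pr3[["precision"]], recall = pr3[["recall"]],
                    f1 = pr3[["f1"]], iou_distribution = dist,
                    boundary = errs),
       recording = recording_agreement(pred_sum, true_sum),
       spo2 = spo2,
       per_night = per_night)
}

#' Run the full pipeline from a configuration
#'
#' simulate -> extract -> occupancy -> train -> predict -> evaluate, with a
#' subject-disjoint stratified split (fold 1 of `folds` is held out).
#'
#' @param config Named list (or path to a YAML file) with entries `cohort`
#'   (n_subjects, severity_mix, night_duration, snr_db), `model` (variant,
#'   base_channels, epochs, lr, batch_size, nr), `folds`, `seed`, and
#'   optionally `out` (JSON report path).
#' @return The evaluation report (invisibly written to `out` if given), with
#'   the resolved configuration and seeds attached for provenance.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  co <- config$cohort %||% list()
  mix <- co$severity_mix %||% c(normal = 0.25, mild = 0.25,
                                moderate = 0.25, severe = 0.25)
  spec <- cohort_spec(n_subjects = co$n_subjects %||% 20L,
                      severity_mix = unlist(mix),
                      night_duration = co$night_duration %||% 600,
                      snr_db = co$snr_db %||% 10,
                      seed = seed)
  nights <- simulate_cohort(spec, verbose = isTRUE(config$verbose))
  subjects <- attr(nights, "subjects")
  folds <- as.integer(config$folds %||% 4L)
  plan <- make_splits(subjects, k = folds, seed = seed)
  test_ids <- plan$id[plan$fold == 1L]
  train_nights <- nights[!(subjects$id %in% test_ids)]
  test_nights <- nights[subjects$id %in% test_ids]
  mc <- config$model %||% list()
  cfg <- segmenter_config(nr = mc$nr %||% 12L,
                          base_channels = mc$base_channels %||% 8L,
                          variant = mc$variant %||% "full")
  model <- train_segmenter(cohort_windows(train_nights, "train"), cfg,
                           epochs = mc$epochs %||% 30L,
                           batch_size = mc$batch_size %||% 32L,
                           lr = mc$lr %||% 1e-3,
                           seed = seed,
                           verbose = isTRUE(config$verbose))
  report <- evaluate_nights(model, test_nights)
  report$config <- list(cohort = spec[c("n_subjects", "night_duration", "snr_db")],
                        severity_mix = as.list(spec$severity_mix),
                        model = cfg[c("variant", "nr", "channels")],
                        folds = folds, seed = seed,
                        test_subjects = test_ids)
  report$history <- model$history
  report$model <- model
  if (!is.null(config$out)) {
    export <- report[c("event", "recording", "spo2", "config")]
    export$recording$confusion <- as.data.frame(report$recording$confusion)
    jsonlite::write_json(export, config$out, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The standard synthetic recovery benchmark
#'
#' Twenty 10-minute nights at 10 dB IF SNR with events of 15-60 s, five
#' subjects per severity grade so recording-level metrics exercise every
#' grade. [run_benchmark()] holds out one stratified fold (5 subjects),
#' trains a small segmenter on the rest and evaluates event- and
#' recording-level performance on the held-out nights.
#'
#' @param seed Master seed for simulation, split, and training.
#' @param n_subjects Cohort size.
#' @param night_duration Night length, s.
#' @param snr_db IF signal-to-noise ratio, dB.
#' @return `benchmark_cohort`: list of `sim_night`s (see [simulate_cohort()]).
#' @export
benchmark_cohort <- function(seed = 1L, n_subjects = 20L,
                             night_duration = 600, snr_db = 10) {
  spec <- cohort_spec(n_subjects = n_subjects,
                      severity_mix = c(normal = 0.25, mild = 0.25,
                                       moderate = 0.25, severe = 0.25),
                      night_duration = night_duration, snr_db = snr_db,
                      seed = seed)
  simulate_cohort(spec)
}

#' @rdname benchmark_cohort
#' @param nights A cohort from [benchmark_cohort()].
#' @param variant Model variant (see [segmenter_config()]).
#' @param base_channels,epochs,lr,batch_size Desk-scale training settings.
#' @param verbose Print per-epoch losses.
#' @return `run_benchmark`: the [evaluate_nights()] report plus `model` and
#'   `test_ids`.
#' @export
run_benchmark <- function(nights, variant = "full", seed = 1L,
                          base_channels = 4L, epochs = 45L, lr = 3e-3,
                          batch_size = 32L, verbose = FALSE) {
  subjects <- attr(nights, "subjects")
  plan <- make_splits(subjects, k = 4L, seed = seed)
  test_ids <- plan$id[plan$fold == 1L]
  train_nights <- nights[!(subjects$id %in% test_ids)]
  test_nights <- nights[subjects$id %in% test_ids]
  cfg <- segmenter_config(nr = 12L, base_channels = base_channels,
                          variant = variant)
  model <- train_segmenter(cohort_windows(train_nights, "train"), cfg,
                           epochs = epochs, batch_size = batch_size, lr = lr,
                           seed = seed, augment_channels = TRUE,
                           verbose = verbose)
  report <- evaluate_nights(model, test_nights)
  report$model <- model
  report$test_ids <- test_ids
  report
}
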