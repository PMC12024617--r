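# Event-level and recording-level evaluation: probability-trace cleaning,
# interval IOU matching, precision/recall/F1, IOU-bin distribution, boundary
# errors, REI with AASM severity grading, and paired-recording agreement.

#' Convert a probability trace into cleaned event intervals
#'
#' Thresholds the per-sample probabilities into binary runs, then corrects
#' prediction jitter: gaps shorter than 1 s between runs are merged first, and
#' events lasting less than 6 s are removed second (events of exactly 6 s are
#' kept). Sample i covers the half-open interval `[(i-1)/fs, i/fs)`.
#'
#' @param prob Per-sample event probabilities in `[0, 1]`.
#' @param fs Sampling rate, Hz.
#' @param threshold Binarization threshold.
#' @param merge_gap Gaps strictly shorter than this (s) are merged.
#' @param min_duration Events strictly shorter than this (s) are removed.
#' @return An [event_set()] with type `"abnormal"`.
#' @export
clean_events <- function(prob, fs, threshold = 0.5, merge_gap = 1,
                         min_duration = 6) {
  if (fs <= 0) stop_invalid("fs must be positive")
  act <- prob >= threshold
  if (!any(act)) return(event_set(type = "abnormal"))
  r <- rle(act)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  iv <- data.frame(start = (starts[keep] - 1) / fs, end = ends[keep] / fs)
  # merge gaps < merge_gap
  merged <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] - merged$end[nrow(merged)] < merge_gap) {
      merged$end[nrow(merged)] <- iv$end[i]
    } else {
      merged <- rbind(merged, iv[i, ])
    }
  }
  # then drop short events
  merged <- merged[merged$end - merged$start >= min_duration, , drop = FALSE]
  event_set(merged$start, merged$end, type = "abnormal", reduction = 0)
}

#' Intersection-over-union of two intervals
#'
#' Each argument is a single `[start, end)` interval (length-2 numeric); the
#' union is measured as total covered length.
#'
#' @param a,b Numeric length-2 vectors `c(start, end)`.
#' @return IOU in `[0, 1]`.
#' @export
interval_iou <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  uni <- (a[2] - a[1]) + (b[2] - b[1]) - inter
  if (uni <= 0) 0 else inter / uni
}

#' Match predicted events to ground-truth events by IOU
#'
#' One-to-one greedy matching over pairs with IOU strictly greater than
#' `iou_min`, taken in order of descending IOU (ties broken by earlier truth
#' start, then earlier prediction start).
#'
#' @param pred,truth [event_set()]s (any labels).
#' @param iou_min Matching criterion; pairs need IOU > `iou_min`.
#' @return A `match_result` list: counts `tp`, `fp`, `fn`; `matches`
#'   data.frame (`pred`, `truth` 1-based indices, `iou`); `unmatched_pred`,
#'   `unmatched_truth` index vectors; and the input sets.
#' @export
match_events <- function(pred, truth, iou_min = 0.1) {
  np <- nrow(pred); nt <- nrow(truth)
  cand <- NULL
  if (np > 0 && nt > 0) {
    ious <- outer(seq_len(np), seq_len(nt), Vectorize(function(i, j) {
      interval_iou(c(pred$start[i], pred$end[i]), c(truth$start[j], truth$end[j]))
    }))
    idx <- which(ious > iou_min, arr.ind = TRUE)
    if (nrow(idx)) {
      cand <- data.frame(pred = idx[, 1], truth = idx[, 2],
                         iou = ious[idx])
      cand <- cand[order(-cand$iou, truth$start[cand$truth],
                         pred$start[cand$pred]), , drop = FALSE]
    }
  }
  matches <- data.frame(pred = integer(), truth = integer(), iou = numeric())
  used_p <- logical(np); used_t <- logical(nt)
  if (!is.null(cand)) {
    for (k in seq_len(nrow(cand))) {
      i <- cand$pred[k]; j <- cand$truth[k]
      if (!used_p[i] && !used_t[j]) {
        used_p[i] <- TRUE; used_t[j] <- TRUE
        matches <- rbind(matches, cand[k, ])
      }
    }
  }
  res <- list(tp = nrow(matches), fp = sum(!used_p), fn = sum(!used_t),
              matches = matches,
              unmatched_pred = which(!used_p), unmatched_truth = which(!used_t),
              pred = pred, truth = truth)
  class(res) <- "match_result"
  res
}

#' Precision, recall and F1 from match counts
#'
#' Zero-denominator metrics are defined as 0 with a warning.
#'
#' @param tp,fp,fn Nonnegative counts.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
prf1 <- function(tp, fp, fn) {
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator for ", what, "; defining it as 0")
      0
    } else {
      num / den
    }
  }
  p <- safe_div(tp, tp + fp, "precision")
  r <- safe_div(tp, tp + fn, "recall")
  f1 <- if (p + r == 0) {
    warning("zero denominator for f1; defining it as 0")
    0
  } else {
    2 * p * r / (p + r)
  }
  c(precision = p, recall = r, f1 = f1)
}

#' Distribution of match IOUs over the standard bins
#'
#' Bins `[0, 0.3)`, `[0.3, 0.6)`, `[0.6, 0.8)`, `[0.8, 1.0]` (half-open except
#' the last). By default the population is matched events only; unmatched
#' truth events may optionally be counted in the lowest bin.
#'
#' @param match A `match_result`.
#' @param include_unmatched Count unmatched truth events in `[0, 0.3)`.
#' @return Named numeric vector of per-bin fractions (summing to 1), or zeros
#'   with a warning for an empty population.
#' @export
iou_distribution <- function(match, include_unmatched = FALSE) {
  ious <- match$matches$iou
  if (include_unmatched) ious <- c(ious, rep(0, length(match$unmatched_truth)))
  labels <- c("0.0-0.3", "0.3-0.6", "0.6-0.8", "0.8-1.0")
  if (length(ious) == 0) {
    warning("empty IOU population; returning zeros")
    return(stats::setNames(rep(0, 4), labels))
  }
  counts <- c(sum(ious < 0.3), sum(ious >= 0.3 & ious < 0.6),
              sum(ious >= 0.6 & ious < 0.8), sum(ious >= 0.8))
  stats::setNames(counts / length(ious), labels)
}

#' Boundary errors of matched events
#'
#' Signed errors (prediction minus truth) in seconds for event start, end and
#' duration, with mean/SD summaries.
#'
#' @param match A `match_result`.
#' @return List with `errors` data.frame (`start`, `end`, `duration`) and
#'   `summary` (mean and SD per column).
#' @export
boundary_errors <- function(match) {
  m <- match$matches
  err <- data.frame(
    start = match$pred$start[m$pred] - match$truth$start[m$truth],
    end = match$pred$end[m$pred] - match$truth$end[m$truth]
  )
  err$duration <- err$end - err$start
  list(errors = err,
       summary = rbind(mean = colMeans(err),
                       sd = apply(err, 2, stats::sd)))
}

#' Respiratory event index and AASM severity grade
#'
#' REI = events per hour of time in bed. Grades (lower bound inclusive):
#' normal `[0, 5)`, mild `[5, 15)`, moderate `[15, 30)`, severe `>= 30`.
#'
#' @param events An [event_set()].
#' @param time_in_bed Time in bed, hours.
#' @return A `recording_summary` list: `rei`, `n_events`, `time_in_bed`,
#'   `grade`.
#' @export
rei_and_grade <- function(events, time_in_bed) {
  if (time_in_bed <= 0) stop_invalid("time in bed must be positive")
  rei <- nrow(events) / time_in_bed
  grade <- grade_from_rei(rei)
  out <- list(rei = rei, n_events = nrow(events), time_in_bed = time_in_bed,
              grade = grade)
  class(out) <- "recording_summary"
  out
}

#' Severity grade from an REI value
#' @param rei Events per hour.
#' @return Factor level among normal/mild/moderate/severe.
#' @export
grade_from_rei <- function(rei) {
  cut(rei, breaks = c(-Inf, 5, 15, 30, Inf), right = FALSE,
      labels = c("normal", "mild", "moderate", "severe"))
}

#' Recording-level agreement between predicted and reference summaries
#'
#' Computes the 4x4 severity confusion matrix, accuracy, macro-averaged
#' sensitivity/precision/F1, REI mean absolute error, and Bland-Altman
#' statistics (mean difference and 95% limits of agreement).
#'
#' @param pred,truth Lists of `recording_summary` objects, paired by position.
#' @return List with `confusion`, `accuracy`, `sensitivity`, `precision`,
#'   `f1` (macro averages), `rei_mae`, `bland_altman` (mean_diff, loa_lower,
#'   loa_upper), and the paired REI values.
#' @export
recording_agreement <- function(pred, truth) {
  if (length(pred) != length(truth)) stop_invalid("unpaired summary lists")
  lv <- c("normal", "mild", "moderate", "severe")
  gp <- factor(vapply(pred, function(s) as.character(s$grade), ""), levels = lv)
  gt <- factor(vapply(truth, function(s) as.character(s$grade), ""), levels = lv)
  confusion <- table(truth = gt, pred = gp)
  acc <- sum(diag(confusion)) / sum(confusion)
  per_class <- function(k) {
    tp <- confusion[k, k]
    sens <- if (sum(confusion[k, ]) == 0) NA_real_ else tp / sum(confusion[k, ])
    prec <- if (sum(confusion[, k]) == 0) NA_real_ else tp / sum(confusion[, k])
    f1 <- if (is.na(sens) || is.na(prec) || sens + prec == 0) NA_real_ else {
      2 * sens * prec / (sens + prec)
    }
    c(sens = sens, prec = prec, f1 = f1)
  }
  pc <- vapply(seq_along(lv), per_class, numeric(3))
  rp <- vapply(pred, function(s) s$rei, numeric(1))
  rt <- vapply(truth, function(s) s$rei, numeric(1))
  d <- rp - rt
  list(confusion = confusion,
       accuracy = acc,
       sensitivity = mean(pc["sens", ], na.rm = TRUE),
       precision = mean(pc["prec", ], na.rm = TRUE),
       f1 = mean(pc["f1", ], na.rm = TRUE),
       rei_mae = mean(abs(d)),
       bland_altman = c(mean_diff = mean(d),
                        loa_lower = mean(d) - 1.96 * stats::sd(d),
                        loa_upper = mean(d) + 1.96 * stats::sd(d)),
       rei_pred = rp, rei_truth = rt)
}
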