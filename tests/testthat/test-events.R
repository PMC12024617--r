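test_that("clean_events applies threshold, merge-then-remove, in that order", {
  fs <- 10
  # all below threshold
  expect_equal(nrow(clean_events(rep(0.1, 100), fs)), 0L)

  # two runs with a 0.5 s gap merge into one 14 s event and survive
  prob <- rep(0, 400)
  prob[(20 * fs + 1):(27 * fs)] <- 0.9
  prob[(27.5 * fs + 1):(34 * fs)] <- 0.9
  ev <- clean_events(prob, fs)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start, 20)
  expect_equal(ev$end, 34)

  # an isolated 5 s run is removed
  prob2 <- rep(0, 300)
  prob2[(10 * fs + 1):(15 * fs)] <- 0.9
  expect_equal(nrow(clean_events(prob2, fs)), 0L)

  # exactly 6 s is kept
  prob3 <- rep(0, 300)
  prob3[(10 * fs + 1):(16 * fs)] <- 0.9
  expect_equal(nrow(clean_events(prob3, fs)), 1L)
  expect_error(clean_events(prob3, 0), "fs")
})

test_that("merge-then-remove order is pinned: two 5 s runs with a 0.5 s gap survive", {
  fs <- 10
  prob <- rep(0, 400)
  prob[(20 * fs + 1):(25 * fs)] <- 1      # 5 s
  prob[(25.5 * fs + 1):(30.5 * fs)] <- 1  # 5 s, 0.5 s gap
  ev <- clean_events(prob, fs)            # merged: 10.5 s, kept
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$end - ev$start, 10.5)
  # remove-then-merge would have deleted both runs first; pin the difference
  runs_removed_first <- nrow(clean_events(prob, fs, merge_gap = 0))
  expect_equal(runs_removed_first, 0L)
})

test_that("clean_events is idempotent on its own output", {
  set.seed(21)
  fs <- 10
  prob <- as.numeric(runif(6000) > 0.7)
  ev1 <- clean_events(prob, fs)
  bin <- label_trace(ev1, 600, fs)
  ev2 <- clean_events(bin, fs)
  expect_equal(ev1$start, ev2$start)
  expect_equal(ev1$end, ev2$end)
})

test_that("interval IOU follows set arithmetic", {
  expect_equal(interval_iou(c(0, 10), c(0, 10)), 1)
  expect_equal(interval_iou(c(0, 10), c(20, 30)), 0)
  expect_equal(interval_iou(c(0, 10), c(5, 15)), 1 / 3)
})

test_that("matching uses strict IOU > 0.1 and is one-to-one", {
  truth <- event_set(0, 10, "abnormal", 0)
  pred_low <- event_set(9, 20, "abnormal", 0)    # IOU 0.05
  m <- match_events(pred_low, truth)
  expect_equal(c(m$tp, m$fp, m$fn), c(0, 1, 1))

  pred_ok <- event_set(2, 12, "abnormal", 0)     # IOU 8/12
  m2 <- match_events(pred_ok, truth)
  expect_equal(m2$tp, 1)
  expect_equal(m2$matches$iou, 8 / 12)

  # exactly at the threshold: IOU == 0.1 is not "greater than 0.1"
  # [0,5.5) vs [4.5,10): intersection 1, union 10 -> exactly 0.1 in binary fp
  truth_eq <- event_set(0, 5.5, "abnormal", 0)
  pred_eq <- event_set(4.5, 10, "abnormal", 0)
  expect_identical(interval_iou(c(4.5, 10), c(0, 5.5)), 0.1)
  expect_equal(match_events(pred_eq, truth_eq)$tp, 0)
})

test_that("greedy matching equals the exhaustive oracle on small instances", {
  set.seed(17)
  for (rep in 1:40) {
    truth <- random_event_set(sample(0:6, 1))
    pred <- random_event_set(sample(0:6, 1))
    m <- match_events(pred, truth)
    oracle <- oracle_match(pred, truth)
    expect_lte(m$tp, oracle$tp)
    expect_lte(m$tp, min(nrow(pred), nrow(truth)))
    # IOU graphs here are interval overlaps: greedy attains the optimum
    expect_equal(m$tp, oracle$tp)
  }
})

test_that("precision/recall/F1 handle regular and degenerate counts", {
  expect_equal(unname(prf1(8, 2, 2)), c(0.8, 0.8, 0.8))
  w <- capture_warnings(z <- prf1(0, 0, 0))
  expect_true(all(grepl("zero denominator", w)))
  expect_equal(unname(z), c(0, 0, 0))
  p <- 0.7022; r <- 0.7556
  expect_equal(unname(prf1(7022, 2978, 2271))[3], 2 * p * r / (p + r),
               tolerance = 1e-4)
})

test_that("IOU distribution uses half-open bins and a documented population", {
  mk <- function(ious, unmatched = 0) {
    structure(list(matches = data.frame(iou = ious),
                   unmatched_truth = seq_len(unmatched)),
              class = "match_result")
  }
  expect_equal(unname(iou_distribution(mk(rep(0.9, 4)))), c(0, 0, 0, 1))
  expect_equal(unname(iou_distribution(mk(c(0.2, 0.5, 0.7, 0.9)))),
               rep(0.25, 4))
  expect_equal(unname(iou_distribution(mk(0.6))), c(0, 0, 1, 0))  # 0.6 in [0.6,0.8)
  expect_equal(unname(iou_distribution(mk(c(0.9), unmatched = 1),
                                       include_unmatched = TRUE)),
               c(0.5, 0, 0, 0.5))
  expect_warning(all0 <- iou_distribution(mk(numeric())), "empty")
  expect_equal(sum(all0), 0)
})

test_that("boundary errors are signed prediction minus truth", {
  truth <- event_set(0, 10, "abnormal", 0)
  pred <- event_set(2, 12, "abnormal", 0)
  be <- boundary_errors(match_events(pred, truth))
  expect_equal(be$errors$start, 2)
  expect_equal(be$errors$end, 2)
  expect_equal(be$errors$duration, 0)
  perfect <- boundary_errors(match_events(truth, truth))
  expect_equal(unlist(perfect$errors), c(start = 0, end = 0, duration = 0))
})

test_that("REI and AASM grading use lower-bound-inclusive cutoffs", {
  ev10 <- random_event_set(10)
  s <- rei_and_grade(ev10, 2)
  expect_equal(s$rei, 5)
  expect_equal(as.character(s$grade), "mild")
  expect_equal(as.character(rei_and_grade(random_event_set(4), 1)$grade),
               "normal")
  expect_equal(as.character(rei_and_grade(random_event_set(31), 1)$grade),
               "severe")
  expect_error(rei_and_grade(ev10, 0), "positive")
  # monotone step function
  reis <- seq(0, 50, by = 0.5)
  g <- as.integer(grade_from_rei(reis))
  expect_true(all(diff(g) >= 0))
  expect_equal(as.character(grade_from_rei(c(5, 15, 30))),
               c("mild", "moderate", "severe"))
})

test_that("recording agreement reproduces a hand-computed confusion summary", {
  mk <- function(rei) rei_and_grade(random_event_set(round(rei)), 1)
  truth <- lapply(c(2, 7, 20, 40), mk)
  pred <- lapply(c(3, 16, 22, 35), mk)   # second night mis-graded
  ag <- recording_agreement(pred, truth)
  expect_equal(ag$accuracy, 3 / 4)
  expect_equal(sum(ag$confusion), 4)
  expect_equal(ag$confusion["mild", "moderate"], 1)
  expect_equal(ag$rei_mae, mean(abs(c(3 - 2, 16 - 7, 22 - 20, 35 - 40))))
  d <- c(1, 9, 2, -5)
  expect_equal(unname(ag$bland_altman["mean_diff"]), mean(d))
  expect_equal(unname(ag$bland_altman["loa_upper"]), mean(d) + 1.96 * sd(d))
  # identical predictions: perfect agreement
  ag0 <- recording_agreement(truth, truth)
  expect_equal(ag0$accuracy, 1)
  expect_equal(ag0$rei_mae, 0)
  expect_equal(unname(ag0$bland_altman["mean_diff"]), 0)
  expect_error(recording_agreement(pred[1:2], truth), "unpaired")
})

test_that("macro-averaged grading F1 matches direct recomputation", {
  mk <- function(rei) rei_and_grade(random_event_set(round(rei)), 1)
  set.seed(31)
  true_rei <- c(2, 3, 8, 12, 18, 25, 33, 45, 4, 10)
  pred_rei <- true_rei + rnorm(10, 0, 4)
  truth <- lapply(true_rei, mk)
  pred <- lapply(pmax(pred_rei, 0), mk)
  ag <- recording_agreement(pred, truth)
  cm <- ag$confusion
  f1s <- sapply(1:4, function(k) {
    tp <- cm[k, k]
    sens <- if (sum(cm[k, ]) == 0) NA else tp / sum(cm[k, ])
    prec <- if (sum(cm[, k]) == 0) NA else tp / sum(cm[, k])
    if (is.na(sens) || is.na(prec) || sens + prec == 0) NA
    else 2 * sens * prec / (sens + prec)
  })
  expect_equal(ag$f1, mean(f1s, na.rm = TRUE))
})
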