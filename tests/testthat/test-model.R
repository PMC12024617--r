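# Window length 64 and two channels keep these structural tests fast; the
# full-size benchmark lives in the acceptance suite.

make_easy_windows <- function(n_windows, n = 64, nr = 2, seed = 1) {
  # oscillation whose envelope drops to zero inside the "event" span
  with_local_seed <- radarsomno:::with_local_seed
  with_local_seed(seed, lapply(seq_len(n_windows), function(i) {
    t <- seq_len(n)
    y <- rep(0, n)
    if (i %% 3 != 0) {            # two thirds of windows contain an event
      a <- sample(5:30, 1); b <- a + sample(10:25, 1)
      y[a:min(b, n)] <- 1
    }
    env <- 1 - 0.95 * y
    x <- sapply(seq_len(nr), function(c) {
      env * sin(2 * pi * t / 8 + c) + rnorm(n, 0, 0.05)
    })
    sm <- as.numeric(stats::filter(c(rep(0, 9), y), rep(1 / 10, 10),
                                   sides = 1))[10:(9 + n)]
    list(x = x, y_event = y, y_spo2 = pmax(0.9 - 0.5 * sm, 0))
  }))
}

test_that("model outputs have the contracted shape and range", {
  cfg <- tiny_model_cfg()
  m <- build_model(cfg, seed = 2)
  x <- matrix(rnorm(64 * 2), 64, 2)
  out <- predict_segmenter(m, x)
  expect_length(out$event, 64)
  expect_length(out$spo2, 64)
  expect_true(all(out$event > 0 & out$event < 1))
  expect_true(all(out$spo2 > 0 & out$spo2 < 1))
  expect_error(segmenter_config(n = 100), "divisible")
})

test_that("ablation variants change structure but keep the output contract", {
  x <- matrix(rnorm(64 * 2), 64, 2)
  for (v in c("full", "no_se", "no_mhsa", "plain", "no_spo2_branch")) {
    m <- build_model(tiny_model_cfg(variant = v), seed = 3)
    out <- predict_segmenter(m, x)
    expect_length(out$event, 64)
    if (v == "no_spo2_branch") expect_null(out$spo2) else {
      expect_length(out$spo2, 64)
    }
  }
  # parameter counts drop at realistic widths (at toy widths a conv block can
  # outweigh the attention it replaces, so count at base 8)
  n_par <- sapply(c("full", "no_se", "no_mhsa", "plain", "no_spo2_branch"),
                  function(v) {
    n_parameters(build_model(segmenter_config(nr = 2L, n = 64L,
                                              base_channels = 8L,
                                              variant = v), seed = 3))
  })
  expect_lt(n_par[["no_mhsa"]], n_par[["full"]])
  expect_lt(n_par[["no_se"]], n_par[["full"]])
  expect_lt(n_par[["plain"]], n_par[["no_se"]])
  expect_lt(n_par[["no_spo2_branch"]], n_par[["full"]])
})

test_that("positional encoding is the only breaker of time symmetry", {
  x <- matrix(1, 64, 2)      # constant input
  m0 <- build_model(tiny_model_cfg(pos_encoding = "none"), seed = 4)
  out0 <- predict_segmenter(m0, x)
  expect_lt(diff(range(out0$event)), 1e-10)
  expect_lt(diff(range(out0$spo2)), 1e-10)
  m1 <- build_model(tiny_model_cfg(pos_encoding = "sinusoidal"), seed = 4)
  out1 <- predict_segmenter(m1, x)
  expect_gt(diff(range(out1$event)), 1e-8)
})

test_that("backprop gradients match finite differences", {
  cfg <- tiny_model_cfg()
  m <- build_model(cfg, seed = 7)
  set.seed(42)
  B <- 2
  x <- matrix(rnorm(B * 64 * 2), B * 64, 2)
  ye <- rbinom(B * 64, 1, 0.3)
  ys <- runif(B * 64)
  loss_fn <- function(params) {
    fwd <- radarsomno:::segmenter_fwd(params, m$state, x, cfg, B, train = TRUE)
    radarsomno:::batch_loss_grads(fwd$y_event, ye, fwd$y_spo2, ys, B, 64)$loss
  }
  fwd <- radarsomno:::segmenter_fwd(m$params, m$state, x, cfg, B, train = TRUE)
  lg <- radarsomno:::batch_loss_grads(fwd$y_event, ye, fwd$y_spo2, ys, B, 64)
  grads <- radarsomno:::segmenter_bwd(m$params, fwd, lg$g_event, lg$g_spo2,
                                      cfg, B)
  paths <- list(list("enc", 1, "W"), list("enc", 2, "se", "W2"),
                list("enc", 3, "gamma"), list("bott", "Wq"),
                list("bott", "Wo"), list("dec_event", 2, "W"),
                list("dec_spo2", 4, "se", "W1"), list("head_event", "W"),
                list("head_spo2", "b"))
  set_leaf <- function(tree, path, idx, val) {
    if (length(path) == 0) {
      tree[idx] <- val
      return(tree)
    }
    tree[[path[[1]]]] <- set_leaf(tree[[path[[1]]]], path[-1], idx, val)
    tree
  }
  eps <- 1e-6
  for (pp in paths) {
    g <- grads; p <- m$params
    for (k in pp) {
      g <- g[[k]]; p <- p[[k]]
    }
    for (trial in 1:2) {
      i <- sample(length(p), 1)
      fd <- (loss_fn(set_leaf(m$params, pp, i, p[i] + eps)) -
               loss_fn(set_leaf(m$params, pp, i, p[i] - eps))) / (2 * eps)
      an <- g[i]
      ok <- abs(fd - an) < 1e-6 ||
        abs(fd - an) / (abs(fd) + abs(an)) < 1e-4
      expect_true(ok, label = paste("gradient at", paste(unlist(pp),
                                                         collapse = "/")))
    }
  }
})

test_that("training reduces the Dice loss on easy separable windows", {
  w <- make_easy_windows(60)
  cfg <- tiny_model_cfg()
  m <- train_segmenter(w, cfg, epochs = 6, batch_size = 16, lr = 3e-3,
                       seed = 5)
  expect_equal(nrow(m$history), 6)
  expect_lt(m$history$dice[5], m$history$dice[1])
  expect_lt(m$history$loss[6], m$history$loss[1])
  expect_error(train_segmenter(list(), cfg), "empty")
  # perfect predictions sit at the zero floor of the loss
  wi <- w[[1]]
  expect_equal(dice_loss(wi$y_event, wi$y_event), 0)
  expect_equal(spo2_loss(wi$y_spo2, wi$y_spo2), 0)
})

test_that("training is deterministic given the seed", {
  w <- make_easy_windows(12)
  cfg <- tiny_model_cfg()
  m1 <- train_segmenter(w, cfg, epochs = 2, batch_size = 8, lr = 1e-3, seed = 9)
  m2 <- train_segmenter(w, cfg, epochs = 2, batch_size = 8, lr = 1e-3, seed = 9)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params$enc[[1]]$W, m2$params$enc[[1]]$W)
  # checkpoints round-trip, with a JSON config sidecar
  f <- tempfile(fileext = ".rds")
  save_model(m1, f)
  m3 <- load_model(f)
  x <- w[[1]]$x
  expect_identical(predict_segmenter(m3, x), predict_segmenter(m1, x))
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$variant, m1$cfg$variant)
  unlink(c(f, paste0(f, ".json")))
})

test_that("recording inference slides windows and averages overlaps", {
  cfg <- tiny_model_cfg()   # n = 64 -> 6.4 s windows at 10 Hz
  m <- build_model(cfg, seed = 11)
  ch <- list(values = matrix(rnorm(2000 * 2), 2000, 2), fs = 10)
  class(ch) <- "resp_channels"
  # span exactly one window long -> outputs defined exactly there
  spans1 <- data.frame(start = 10, end = 16.4)
  pr1 <- predict_recording(m, ch, spans1, step = 3)
  expect_equal(sum(!is.na(pr1$event)), 64)
  # longer span: overlap region equals the mean of the two window passes
  spans2 <- data.frame(start = 0, end = 9.4)    # windows at 0 and 3 s
  pr2 <- predict_recording(m, ch, spans2, step = 3)
  w1 <- predict_segmenter(m, ch$values[1:64, ])$event
  w2 <- predict_segmenter(m, ch$values[31:94, ])$event
  overlap_idx <- 31:64
  manual <- (w1[overlap_idx] + w2[overlap_idx - 30]) / 2
  expect_equal(pr2$event[overlap_idx], manual, tolerance = 1e-12)
  # short span: reflect-pad then crop
  spans3 <- data.frame(start = 50, end = 53)
  pr3 <- predict_recording(m, ch, spans3, step = 3)
  expect_equal(sum(!is.na(pr3$event)), 30)
  # SpO2 comes back in percent
  expect_true(all(pr1$spo2_pct[!is.na(pr1$spo2_pct)] >= 80))
})
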