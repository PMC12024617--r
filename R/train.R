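# Training (Adam on the multitask Dice + SpO2 loss) and whole-recording
# windowed inference.

# recurse over parallel nested parameter lists by name (or position when
# unnamed); leaves are numeric arrays
tree_map <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1]]
  if (is.list(t1)) {
    keys <- if (!is.null(names(t1)) && all(nzchar(names(t1)))) names(t1) else seq_along(t1)
    out <- vector("list", length(keys))
    names(out) <- if (is.character(keys)) keys else NULL
    for (k in seq_along(keys)) {
      out[[k]] <- do.call(tree_map, c(list(f), lapply(trees, `[[`, keys[[k]])))
    }
    out
  } else {
    do.call(f, trees)
  }
}

# per-batch multitask loss and its gradient w.r.t. the two sigmoid outputs.
# Dice is computed over the whole batch: averaging it per window starves
# event-free windows of gradient (the empty-mask pathology) and lets the
# model drift high on event-free subjects. The SpO2 composite is per window,
# then averaged (correlation within a window is the clinically meaningful
# trend).
batch_loss_grads <- function(p_event, y_event, p_spo2, y_spo2, bsz, n,
                             eps = 1e-4, lambda_corr = 1, lambda_spo2 = 1) {
  grp <- rep(seq_len(bsz), each = n)
  num <- 2 * sum(p_event * y_event) + eps
  den <- sum(p_event) + sum(y_event) + eps
  l_dice <- 1 - num / den
  g_event <- -(2 * y_event * den - num) / den^2
  l_spo2 <- NULL
  g_spo2 <- NULL
  if (!is.null(p_spo2)) {
    dmae <- p_spo2 - y_spo2
    mae_b <- rowsum(abs(dmae), grp)[, 1] / n
    a <- p_spo2 - (rowsum(p_spo2, grp)[, 1] / n)[grp]
    b <- y_spo2 - (rowsum(y_spo2, grp)[, 1] / n)[grp]
    na2 <- rowsum(a * a, grp)[, 1]
    nb2 <- rowsum(b * b, grp)[, 1]
    cross <- rowsum(a * b, grp)[, 1]
    ok <- na2 > 0 & nb2 > 0
    rho <- ifelse(ok, cross / sqrt(na2 * nb2), 0)
    l_spo2 <- mean(mae_b + lambda_corr * (1 - rho))
    g_spo2 <- sign(dmae) / n
    gc <- ifelse(ok, 1 / sqrt(na2 * nb2), 0)
    gr <- ifelse(ok, rho / na2, 0)
    g_spo2 <- g_spo2 - lambda_corr * (b * gc[grp] - a * gr[grp])
    g_spo2 <- g_spo2 / bsz
  }
  total <- total_loss(l_dice, l_spo2, lambda_spo2)
  list(loss = total, l_dice = l_dice, l_spo2 = l_spo2,
       g_event = g_event,
       g_spo2 = if (!is.null(g_spo2)) lambda_spo2 * g_spo2)
}

#' Train the segmentation model
#'
#' Minimises the total multitask loss (Dice on events plus the MAE +
#' correlation SpO2 loss) with Adam. The reference defaults are batch size
#' 32 and learning rate 1e-5 with standard Adam moments; small desk-scale
#' runs typically use a larger learning rate (see the benchmark helpers).
#'
#' @param windows List of window samples, each a list with `x` (`[n x nr]`
#'   matrix), `y_event` (0/1 vector of length n), `y_spo2` (scaled SpO2
#'   vector; ignored for the single-task variant).
#' @param cfg A [segmenter_config()].
#' @param epochs Training epochs.
#' @param batch_size Windows per batch.
#' @param lr Adam learning rate.
#' @param lambda_spo2,lambda_corr Loss weights.
#' @param seed Seed for weight init and shuffling.
#' @param augment_channels If TRUE, each training window's channels are
#'   randomly permuted and up to `drop_channels` of them zeroed per epoch.
#'   Respiratory channels are ranked bin selections whose per-subject layout
#'   varies (which positions carry breathing versus noise differs from night
#'   to night); permutation forces the network to detect events on whichever
#'   channels carry signal instead of memorising the training subjects'
#'   layouts, markedly improving cross-subject robustness.
#' @param drop_channels Maximum number of channels zeroed per window when
#'   augmenting.
#' @param validation Optional list of windows evaluated after each epoch.
#' @param verbose Print per-epoch losses.
#' @return A `segmenter_model` with a `history` data.frame (per-epoch mean
#'   training losses and optional validation loss).
#' @export
train_segmenter <- function(windows, cfg = segmenter_config(), epochs = 10,
                            batch_size = 32, lr = 1e-5,
                            lambda_spo2 = 1, lambda_corr = 1,
                            seed = 1L, augment_channels = FALSE,
                            drop_channels = 2L,
                            validation = NULL, verbose = FALSE) {
  if (length(windows) == 0) stop_invalid("empty training set")
  model <- build_model(cfg, seed = seed)
  mstate <- tree_map(function(x) x * 0, model$params)
  vstate <- mstate
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  t_step <- 0
  history <- NULL
  with_local_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(windows))
      ep_loss <- ep_dice <- ep_spo2 <- 0
      nb <- 0
      for (ofs in seq(1, length(ord), by = batch_size)) {
        idx <- ord[ofs:min(ofs + batch_size - 1, length(ord))]
        bsz <- length(idx)
        xs <- lapply(windows[idx], `[[`, "x")
        if (augment_channels) {
          xs <- lapply(xs, function(x) {
            x <- x[, sample.int(ncol(x)), drop = FALSE]
            k <- sample(0:drop_channels, 1)
            if (k > 0) x[, sample.int(ncol(x), k)] <- 0
            x
          })
        }
        xb <- do.call(rbind, xs)
        ye <- unlist(lapply(windows[idx], `[[`, "y_event"), use.names = FALSE)
        ys <- if (cfg$use_spo2) {
          unlist(lapply(windows[idx], `[[`, "y_spo2"), use.names = FALSE)
        }
        fwd <- segmenter_fwd(model$params, model$state, xb, cfg, bsz, train = TRUE)
        model$state <- fwd$state
        lg <- batch_loss_grads(fwd$y_event, ye, fwd$y_spo2, ys, bsz, cfg$n,
                               lambda_corr = lambda_corr,
                               lambda_spo2 = lambda_spo2)
        grads <- segmenter_bwd(model$params, fwd, lg$g_event, lg$g_spo2, cfg, bsz)
        t_step <- t_step + 1
        upd <- adam_step(model$params, grads, mstate, vstate, lr, t_step,
                         b1, b2, adam_eps)
        model$params <- upd$p
        mstate <- upd$m
        vstate <- upd$v
        ep_loss <- ep_loss + lg$loss
        ep_dice <- ep_dice + lg$l_dice
        ep_spo2 <- ep_spo2 + if (is.null(lg$l_spo2)) 0 else lg$l_spo2
        nb <- nb + 1
      }
      row <- data.frame(epoch = ep, loss = ep_loss / nb, dice = ep_dice / nb,
                        spo2 = ep_spo2 / nb, val_loss = NA_real_)
      if (!is.null(validation)) {
        row$val_loss <- evaluate_loss(model, validation,
                                      lambda_spo2 = lambda_spo2,
                                      lambda_corr = lambda_corr)
      }
      history <- rbind(history, row)
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f (dice %.4f, spo2 %.4f)",
                        ep, row$loss, row$dice, row$spo2))
      }
    }
  })
  model$history <- history
  model
}

adam_step <- function(p, g, m, v, lr, t, b1, b2, eps) {
  if (is.list(p)) {
    keys <- if (!is.null(names(p)) && all(nzchar(names(p)))) names(p) else seq_along(p)
    for (k in keys) {
      res <- adam_step(p[[k]], g[[k]], m[[k]], v[[k]], lr, t, b1, b2, eps)
      p[[k]] <- res$p; m[[k]] <- res$m; v[[k]] <- res$v
    }
    list(p = p, m = m, v = v)
  } else {
    m2 <- b1 * m + (1 - b1) * g
    v2 <- b2 * v + (1 - b2) * g^2
    mhat <- m2 / (1 - b1^t)
    vhat <- v2 / (1 - b2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m2, v = v2)
  }
}

#' Mean multitask loss of a model over a window set
#'
#' @param model A `segmenter_model`.
#' @param windows Window samples as in [train_segmenter()].
#' @param lambda_spo2,lambda_corr Loss weights.
#' @return Scalar mean loss.
#' @export
evaluate_loss <- function(model, windows, lambda_spo2 = 1, lambda_corr = 1) {
  cfg <- model$cfg
  preds <- predict_segmenter(model, lapply(windows, `[[`, "x"))
  losses <- vapply(seq_along(windows), function(i) {
    ld <- dice_loss(preds[[i]]$event, windows[[i]]$y_event)
    ls <- if (cfg$use_spo2) {
      spo2_loss(preds[[i]]$spo2, windows[[i]]$y_spo2, lambda_corr)
    }
    total_loss(ld, ls, lambda_spo2)
  }, numeric(1))
  mean(losses)
}

#' Windowed inference over the time-in-bed spans of a recording
#'
#' Slides 204.8 s windows at a fixed 30 s step inside each span (a final
#' window is aligned to the span end so the tail is covered); overlapping
#' per-sample probabilities are combined by arithmetic mean. Spans shorter
#' than one window are left-padded by reflection and cropped. SpO2 outputs
#' are inverse-scaled to percent.
#'
#' @param model A trained `segmenter_model`.
#' @param channels A `resp_channels` object covering the whole recording.
#' @param spans data.frame of Lie-in-Bed spans (`start`, `end` in s).
#' @param step Window step, s.
#' @param batch_windows Windows evaluated per forward pass.
#' @return List with `event` (probability trace, NA outside spans), `spo2_pct`
#'   (NA outside spans or for single-task models), and `fs`.
#' @export
predict_recording <- function(model, channels, spans, step = 30,
                              batch_windows = 16L) {
  cfg <- model$cfg
  fs <- channels$fs
  n <- cfg$n
  win_s <- n / fs
  total <- nrow(channels$values)
  acc_e <- rep(0, total); acc_s <- rep(0, total); cnt <- rep(0, total)
  jobs <- list()   # each: list(x, rows, crop)
  for (k in seq_len(nrow(spans))) {
    i0 <- time_to_index(spans$start[k], fs)
    i1 <- min(time_to_index(spans$end[k], fs) - 1L, total)
    len <- i1 - i0 + 1L
    if (len <= 0) next
    if (len < n) {
      x <- channels$values[i0:i1, , drop = FALSE]
      pad <- n - len
      refl <- x[pmin(rev(seq_len(pad)) %% (2 * len - 2) + 1, len), , drop = FALSE]
      jobs[[length(jobs) + 1]] <- list(x = rbind(refl, x), rows = i0:i1,
                                       crop = (pad + 1):n)
    } else {
      offs <- seq(0, len - n, by = round(step * fs))
      if (max(offs) < len - n) offs <- c(offs, len - n)
      for (o in offs) {
        rows <- (i0 + o):(i0 + o + n - 1L)
        jobs[[length(jobs) + 1]] <- list(x = channels$values[rows, , drop = FALSE],
                                         rows = rows, crop = seq_len(n))
      }
    }
  }
  for (ofs in seq(1, length(jobs), by = batch_windows)) {
    idx <- ofs:min(ofs + batch_windows - 1L, length(jobs))
    preds <- predict_segmenter(model, lapply(jobs[idx], `[[`, "x"))
    for (j in seq_along(idx)) {
      jb <- jobs[[idx[j]]]
      acc_e[jb$rows] <- acc_e[jb$rows] + preds[[j]]$event[jb$crop]
      if (!is.null(preds[[j]]$spo2)) {
        acc_s[jb$rows] <- acc_s[jb$rows] + preds[[j]]$spo2[jb$crop]
      }
      cnt[jb$rows] <- cnt[jb$rows] + 1
    }
  }
  covered <- cnt > 0
  ev <- rep(NA_real_, total); sp <- rep(NA_real_, total)
  ev[covered] <- acc_e[covered] / cnt[covered]
  if (cfg$use_spo2) sp[covered] <- inv_scale_spo2(acc_s[covered] / cnt[covered])
  list(event = ev, spo2_pct = sp, fs = fs)
}
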