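# The multitask segmentation network: a 1D U-Net whose encoder blocks are
# Convolution-BN-ReLU-SE, whose bottleneck is positional encoding plus
# multihead self-attention, and whose twin decoders emit per-sample event
# probability and scaled SpO2.

#' Model configuration
#'
#' @param nr Number of input respiratory channels.
#' @param n Window length in samples (must be divisible by `2^depth`).
#' @param depth Encoder/decoder blocks (temporal length halves per block).
#' @param base_channels Channels of the first block; doubled per block.
#' @param se_ratio Squeeze-and-excitation reduction ratio.
#' @param n_heads Attention heads in the bottleneck.
#' @param pos_encoding `"sinusoidal"` or `"none"`.
#' @param variant Ablation variant: `"full"` (SE + MHSA), `"no_se"`,
#'   `"no_mhsa"`, `"plain"` (neither; bottleneck is a convolutional block),
#'   or `"no_spo2_branch"` (full attention model, single-task).
#' @return An object of class `segmenter_config`.
#' @export
segmenter_config <- function(nr = 12L, n = 2048L, depth = 4L,
                             base_channels = 32L, se_ratio = 8L, n_heads = 4L,
                             pos_encoding = c("sinusoidal", "none"),
                             variant = c("full", "no_se", "no_mhsa", "plain",
                                         "no_spo2_branch")) {
  variant <- match.arg(variant)
  pos_encoding <- match.arg(pos_encoding)
  if (n %% 2^depth != 0) {
    stop_invalid("window length must be divisible by 2^depth")
  }
  channels <- base_channels * 2^(seq_len(depth) - 1)
  use_se <- !(variant %in% c("no_se", "plain"))
  use_mhsa <- !(variant %in% c("no_mhsa", "plain"))
  cfg <- list(nr = as.integer(nr), n = as.integer(n), depth = as.integer(depth),
              channels = as.integer(channels), se_ratio = as.integer(se_ratio),
              n_heads = as.integer(n_heads), pos_encoding = pos_encoding,
              variant = variant, use_se = use_se, use_mhsa = use_mhsa,
              use_spo2 = variant != "no_spo2_branch")
  class(cfg) <- "segmenter_config"
  cfg
}

init_block <- function(cin, cout, cfg) {
  p <- list(W = matrix(stats::rnorm(3 * cin * cout, 0, sqrt(2 / (3 * cin))),
                       3 * cin, cout),
            b = rep(0, cout),
            gamma = rep(1, cout), beta = rep(0, cout))
  if (cfg$use_se) {
    cr <- max(1L, cout %/% cfg$se_ratio)
    p$se <- list(W1 = matrix(stats::rnorm(cout * cr, 0, sqrt(2 / cout)), cout, cr),
                 b1 = rep(0, cr),
                 W2 = matrix(stats::rnorm(cr * cout, 0, sqrt(2 / cr)), cr, cout),
                 b2 = rep(0, cout))
  }
  p
}

#' Build (initialise) a segmenter model
#'
#' @param cfg A [segmenter_config()].
#' @param seed RNG seed for weight initialisation.
#' @return An object of class `segmenter_model` holding `params` (trainable),
#'   `state` (batch-norm running statistics), and `cfg`.
#' @export
build_model <- function(cfg = segmenter_config(), seed = 1L) {
  with_local_seed(seed, {
    ch <- cfg$channels
    d <- cfg$depth
    params <- list(enc = vector("list", d),
                   dec_event = vector("list", d))
    cin <- cfg$nr
    for (i in seq_len(d)) {
      params$enc[[i]] <- init_block(cin, ch[i], cfg)
      cin <- ch[i]
    }
    cd <- ch[d]
    if (cfg$use_mhsa) {
      sdv <- sqrt(1 / cd)
      params$bott <- list(Wq = matrix(stats::rnorm(cd * cd, 0, sdv), cd, cd),
                          Wk = matrix(stats::rnorm(cd * cd, 0, sdv), cd, cd),
                          Wv = matrix(stats::rnorm(cd * cd, 0, sdv), cd, cd),
                          Wo = matrix(stats::rnorm(cd * cd, 0, sdv), cd, cd),
                          bo = rep(0, cd))
    } else {
      params$bott <- init_block(cd, cd, cfg)
    }
    dec_channels <- function() {
      blocks <- vector("list", d)
      for (i in rev(seq_len(d))) {
        cin_dec <- if (i == d) ch[d] + ch[d] else ch[i + 1] + ch[i]
        blocks[[i]] <- init_block(cin_dec, ch[i], cfg)
      }
      blocks
    }
    params$dec_event <- dec_channels()
    params$head_event <- list(W = matrix(stats::rnorm(ch[1], 0, sqrt(1 / ch[1])),
                                         ch[1], 1), b = 0)
    if (cfg$use_spo2) {
      params$dec_spo2 <- dec_channels()
      params$head_spo2 <- list(W = matrix(stats::rnorm(ch[1], 0, sqrt(1 / ch[1])),
                                          ch[1], 1), b = 0)
    }
    state <- init_bn_state(params)
    m <- list(params = params, state = state, cfg = cfg)
    class(m) <- "segmenter_model"
    m
  })
}

# one running-stats entry per BN layer, addressed by path name
init_bn_state <- function(params) {
  st <- list()
  add <- function(name, p) {
    if (!is.null(p$gamma)) {
      st[[name]] <<- list(mean = rep(0, length(p$gamma)),
                          var = rep(1, length(p$gamma)))
    }
  }
  for (i in seq_along(params$enc)) add(paste0("enc", i), params$enc[[i]])
  add("bott", params$bott)
  for (i in seq_along(params$dec_event)) {
    add(paste0("dec_event", i), params$dec_event[[i]])
  }
  if (!is.null(params$dec_spo2)) {
    for (i in seq_along(params$dec_spo2)) {
      add(paste0("dec_spo2", i), params$dec_spo2[[i]])
    }
  }
  st
}

# conv-bn-relu(-se) block
block_fwd <- function(x, p, st, cfg, bsz, n, train) {
  cv <- conv3_fwd(x, p$W, p$b, n)
  bn <- bn_fwd(cv$y, p$gamma, p$beta, st, train)
  a <- bn$y
  relu_mask <- a > 0
  a <- a * relu_mask
  cache <- list(cv = cv, bn = bn, relu_mask = relu_mask, x = x, a_pre_se = a)
  if (cfg$use_se) {
    grp <- rep(seq_len(bsz), each = n)
    se <- se_fwd(a, p$se, grp, n)
    cache$se <- se
    cache$grp <- grp
    a <- se$y
  }
  list(y = a, cache = cache, running = bn$running)
}
block_bwd <- function(dy, cache, p, cfg, bsz, n) {
  g <- list()
  if (cfg$use_se) {
    sb <- se_bwd(dy, cache$se, cache$a_pre_se, p$se, cache$grp, n)
    g$se <- list(W1 = sb$dW1, b1 = sb$db1, W2 = sb$dW2, b2 = sb$db2)
    dy <- sb$dx
  }
  dy <- dy * cache$relu_mask
  bb <- bn_bwd(dy, cache$bn, p$gamma)
  g$gamma <- bb$dgamma
  g$beta <- bb$dbeta
  cin <- ncol(cache$x)
  cb <- conv3_bwd(bb$dx, cache$cv, p$W, n, cin)
  g$W <- cb$dW
  g$b <- cb$db
  list(dx = cb$dx, g = g)
}

# full forward pass; returns sigmoid outputs and caches for backprop
segmenter_fwd <- function(params, state, x, cfg, bsz, train = FALSE) {
  d <- cfg$depth
  n <- cfg$n
  caches <- list(enc = vector("list", d), pool = vector("list", d),
                 dec_event = vector("list", d), dec_spo2 = vector("list", d))
  skips <- vector("list", d)
  cur <- x
  len <- n
  for (i in seq_len(d)) {
    bl <- block_fwd(cur, params$enc[[i]], state[[paste0("enc", i)]],
                    cfg, bsz, len, train)
    state[[paste0("enc", i)]] <- bl$running
    caches$enc[[i]] <- bl$cache
    skips[[i]] <- bl$y
    pl <- pool2_fwd(bl$y)
    caches$pool[[i]] <- pl
    cur <- pl$y
    len <- len %/% 2
  }
  tlen <- len
  if (cfg$use_mhsa) {
    if (cfg$pos_encoding == "sinusoidal") {
      pe <- positional_encoding(tlen, ncol(cur))
      cur <- cur + pe[rep(seq_len(tlen), times = bsz), , drop = FALSE]
    }
    mh <- mhsa_fwd(cur, params$bott, bsz, tlen, cfg$n_heads)
    caches$bott <- mh
    cur <- mh$y
  } else {
    bl <- block_fwd(cur, params$bott, state$bott, cfg, bsz, tlen, train)
    state$bott <- bl$running
    caches$bott <- bl$cache
    cur <- bl$y
  }
  decode <- function(bottom, which) {
    cur <- bottom
    len <- tlen
    dcaches <- vector("list", d)
    for (i in rev(seq_len(d))) {
      up <- upsample2_fwd(cur)
      len <- len * 2
      cat_in <- cbind(up, skips[[i]])
      key <- paste0(which, i)
      bl <- block_fwd(cat_in, params[[which]][[i]], state[[key]],
                      cfg, bsz, len, train)
      state[[key]] <<- bl$running
      dcaches[[i]] <- list(block = bl$cache, up_cols = ncol(up))
      cur <- bl$y
    }
    list(y = cur, caches = dcaches)
  }
  de <- decode(cur, "dec_event")
  ze <- conv1_fwd(de$y, params$head_event$W, params$head_event$b)
  y_event <- sigmoid(ze)
  caches$dec_event <- de$caches
  caches$head_event <- list(x = de$y, z = ze)
  y_spo2 <- NULL
  if (cfg$use_spo2) {
    ds <- decode(cur, "dec_spo2")
    zs <- conv1_fwd(ds$y, params$head_spo2$W, params$head_spo2$b)
    y_spo2 <- sigmoid(zs)
    caches$dec_spo2 <- ds$caches
    caches$head_spo2 <- list(x = ds$y, z = zs)
  }
  caches$bottom <- cur
  list(y_event = as.numeric(y_event), y_spo2 = if (!is.null(y_spo2)) as.numeric(y_spo2),
       caches = caches, state = state)
}

# full backward pass: dy_event / dy_spo2 are gradients w.r.t. the sigmoid
# outputs; returns gradients in the same nested structure as params
segmenter_bwd <- function(params, fwd, dy_event, dy_spo2, cfg, bsz) {
  d <- cfg$depth
  caches <- fwd$caches
  grads <- list(enc = vector("list", d), dec_event = vector("list", d))
  # event head
  pe <- fwd$y_event
  dz <- matrix(dy_event * pe * (1 - pe), ncol = 1)
  hb <- conv1_bwd(dz, caches$head_event$x, params$head_event$W)
  grads$head_event <- list(W = hb$dW, b = hb$db)
  d_bottom <- NULL
  decode_bwd <- function(dcur, which, dcaches) {
    dskips <- vector("list", d)
    gblocks <- vector("list", d)
    len <- cfg$n
    for (i in seq_len(d)) {
      bb <- block_bwd(dcur, dcaches[[i]]$block, params[[which]][[i]], cfg, bsz, len)
      gblocks[[i]] <- bb$g
      uc <- dcaches[[i]]$up_cols
      dskips[[i]] <- bb$dx[, (uc + 1):ncol(bb$dx), drop = FALSE]
      dup <- bb$dx[, 1:uc, drop = FALSE]
      dcur <- upsample2_bwd(dup)
      len <- len %/% 2
    }
    list(d_bottom = dcur, dskips = dskips, g = gblocks)
  }
  ev <- decode_bwd(hb$dx, "dec_event", caches$dec_event)
  grads$dec_event <- ev$g
  d_bottom <- ev$d_bottom
  dskips <- ev$dskips
  if (cfg$use_spo2) {
    ps <- fwd$y_spo2
    dzs <- matrix(dy_spo2 * ps * (1 - ps), ncol = 1)
    hs <- conv1_bwd(dzs, caches$head_spo2$x, params$head_spo2$W)
    grads$head_spo2 <- list(W = hs$dW, b = hs$db)
    sp <- decode_bwd(hs$dx, "dec_spo2", caches$dec_spo2)
    grads$dec_spo2 <- sp$g
    d_bottom <- d_bottom + sp$d_bottom
    for (i in seq_len(d)) dskips[[i]] <- dskips[[i]] + sp$dskips[[i]]
  }
  tlen <- cfg$n %/% 2^d
  if (cfg$use_mhsa) {
    mb <- mhsa_bwd(d_bottom, caches$bott, params$bott, bsz, tlen, cfg$n_heads)
    grads$bott <- mb[c("Wq", "Wk", "Wv", "Wo", "bo")]
    dcur <- mb$dx  # positional encoding is additive: gradient passes through
  } else {
    bb <- block_bwd(d_bottom, caches$bott, params$bott, cfg, bsz, tlen)
    grads$bott <- bb$g
    dcur <- bb$dx
  }
  len <- tlen
  for (i in rev(seq_len(d))) {
    dpool <- pool2_bwd(dcur, caches$pool[[i]])
    len <- len * 2
    dpool <- dpool + dskips[[i]]
    bb <- block_bwd(dpool, caches$enc[[i]], params$enc[[i]], cfg, bsz, len)
    grads$enc[[i]] <- bb$g
    dcur <- bb$dx
  }
  grads
}

#' Number of trainable parameters of a model
#' @param model A `segmenter_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  total <- 0
  walk <- function(p) {
    if (is.list(p)) lapply(p, walk) else total <<- total + length(p)
    invisible(NULL)
  }
  walk(model$params)
  total
}

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS of the weights, batch-norm state, configuration
#' and training history, with a human-readable JSON sidecar
#' (`<path>.json`) describing the configuration.
#'
#' @param model A `segmenter_model`.
#' @param path Checkpoint path (e.g. `model.rds`).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored `segmenter_model`.
#' @export
save_model <- function(model, path) {
  saveRDS(unclass(model), path)
  jsonlite::write_json(model$cfg[c("nr", "n", "depth", "channels", "se_ratio",
                                   "n_heads", "pos_encoding", "variant")],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  class(m$cfg) <- "segmenter_config"
  class(m) <- "segmenter_model"
  m
}

#' Forward-pass prediction for windows
#'
#' @param model A trained `segmenter_model`.
#' @param x A single `[n x nr]` matrix or list of them.
#' @return For one window, list with `event` and `spo2` probability vectors
#'   (length n, values in (0, 1); `spo2` is NULL for the single-task
#'   variant); for a list input, a list of such lists.
#' @export
predict_segmenter <- function(model, x) {
  single <- is.matrix(x)
  xs <- if (single) list(x) else x
  cfg <- model$cfg
  xb <- do.call(rbind, xs)
  fwd <- segmenter_fwd(model$params, model$state, xb, cfg, length(xs),
                       train = FALSE)
  out <- lapply(seq_along(xs), function(b) {
    rows <- (b - 1) * cfg$n + seq_len(cfg$n)
    list(event = fwd$y_event[rows],
         spo2 = if (!is.null(fwd$y_spo2)) fwd$y_spo2[rows])
  })
  if (single) out[[1]] else out
}
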