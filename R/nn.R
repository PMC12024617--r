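# Neural-network primitives with explicit forward/backward passes.
#
# Tensors are stored as matrices of shape [(B*N) x C]: B windows stacked
# batch-major along the rows, N samples per window, C channels in columns.
# All heavy lifting is BLAS matrix multiplication. Gradient correctness is
# pinned by finite-difference tests.

sigmoid <- function(x) 1 / (1 + exp(-x))

# row shifts within batch blocks of length n (edge-replicate padding, so a
# time-constant input stays time-constant through a convolution)
shift_prev_rep <- function(x, n) {
  r <- nrow(x)
  y <- x
  y[2:r, ] <- x[1:(r - 1), ]
  first <- seq(1, r, by = n)
  y[first, ] <- x[first, ]
  y
}
shift_next_rep <- function(x, n) {
  r <- nrow(x)
  y <- x
  y[1:(r - 1), ] <- x[2:r, ]
  last <- seq(n, r, by = n)
  y[last, ] <- x[last, ]
  y
}
# adjoints of the two shifts
shift_prev_rep_adj <- function(dy, n) {
  r <- nrow(dy)
  dx <- matrix(0, r, ncol(dy))
  dx[1:(r - 1), ] <- dy[2:r, ]
  dx[seq(n, r, by = n), ] <- 0
  first <- seq(1, r, by = n)
  dx[first, ] <- dx[first, ] + dy[first, ]
  dx
}
shift_next_rep_adj <- function(dy, n) {
  r <- nrow(dy)
  dx <- matrix(0, r, ncol(dy))
  dx[2:r, ] <- dy[1:(r - 1), ]
  dx[seq(1, r, by = n), ] <- 0
  last <- seq(n, r, by = n)
  dx[last, ] <- dx[last, ] + dy[last, ]
  dx
}

# kernel-3 "same" 1D convolution ---------------------------------------------
# y = P(x Wm) + x W0 + N(x Wp), with P/N the edge-replicating row shifts, so
# the three taps become three GEMMs and the shifts act on the smaller outputs
conv3_fwd <- function(x, W, b, n) {
  cin <- ncol(x)
  y <- shift_prev_rep(x %*% W[1:cin, , drop = FALSE], n) +
    x %*% W[cin + (1:cin), , drop = FALSE] +
    shift_next_rep(x %*% W[2 * cin + (1:cin), , drop = FALSE], n)
  y <- y + rep(b, each = nrow(y))
  list(y = y, x = x)
}
conv3_bwd <- function(dy, cache, W, n, cin) {
  x <- cache$x
  da <- shift_prev_rep_adj(dy, n)
  dc <- shift_next_rep_adj(dy, n)
  dW <- rbind(crossprod(x, da), crossprod(x, dy), crossprod(x, dc))
  db <- colSums(dy)
  dx <- da %*% t(W[1:cin, , drop = FALSE]) +
    dy %*% t(W[cin + (1:cin), , drop = FALSE]) +
    dc %*% t(W[2 * cin + (1:cin), , drop = FALSE])
  list(dx = dx, dW = dW, db = db)
}

# kernel-1 convolution (pointwise linear map) ---------------------------------
conv1_fwd <- function(x, W, b) {
  y <- x %*% W
  y + rep(b, each = nrow(y))
}
conv1_bwd <- function(dy, x, W) {
  list(dx = dy %*% t(W), dW = crossprod(x, dy), db = colSums(dy))
}

# batch normalisation over all rows, per channel ------------------------------
BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9
bn_fwd <- function(x, gamma, beta, running, train) {
  r <- nrow(x)
  if (train) {
    mu <- colMeans(x)
    xc <- x - rep(mu, each = r)
    v <- colMeans(xc^2)
    running$mean <- BN_MOMENTUM * running$mean + (1 - BN_MOMENTUM) * mu
    running$var <- BN_MOMENTUM * running$var + (1 - BN_MOMENTUM) * v
  } else {
    mu <- running$mean
    v <- running$var
    xc <- x - rep(mu, each = r)
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  xhat <- xc * rep(invstd, each = r)
  y <- xhat * rep(gamma, each = r) + rep(beta, each = r)
  list(y = y, xhat = xhat, invstd = invstd, running = running)
}
bn_bwd <- function(dy, cache, gamma) {
  r <- nrow(dy)
  dxhat <- dy * rep(gamma, each = r)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dx <- dxhat - rep(s1 / r, each = r) - cache$xhat * rep(s2 / r, each = r)
  dx <- dx * rep(cache$invstd, each = r)
  list(dx = dx, dgamma = colSums(dy * cache$xhat), dbeta = colSums(dy))
}

# squeeze-and-excitation ------------------------------------------------------
se_fwd <- function(x, p, grp, n) {
  s <- rowsum(x, grp, reorder = TRUE) / n                 # [B x C]
  h <- pmax(s %*% p$W1 + matrix(p$b1, nrow(s), length(p$b1), byrow = TRUE), 0)
  z <- h %*% p$W2 + matrix(p$b2, nrow(h), length(p$b2), byrow = TRUE)
  w <- sigmoid(z)                                          # [B x C]
  wx <- w[grp, , drop = FALSE]
  list(y = x * wx, s = s, h = h, w = w, wx = wx)
}
se_bwd <- function(dy, cache, x, p, grp, n) {
  dx <- dy * cache$wx
  dw <- rowsum(dy * x, grp, reorder = TRUE)                # [B x C]
  dz <- dw * cache$w * (1 - cache$w)
  dW2 <- crossprod(cache$h, dz)
  db2 <- colSums(dz)
  dh <- dz %*% t(p$W2)
  dh[cache$h <= 0] <- 0
  dW1 <- crossprod(cache$s, dh)
  db1 <- colSums(dh)
  ds <- dh %*% t(p$W1)
  dx <- dx + ds[grp, , drop = FALSE] / n
  list(dx = dx, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

# max pooling / nearest upsampling by 2 along time ----------------------------
pool2_fwd <- function(x) {
  r <- nrow(x)
  odd <- seq(1, r, by = 2)
  a <- x[odd, , drop = FALSE]
  b <- x[odd + 1, , drop = FALSE]
  m <- a >= b
  list(y = pmax(a, b), mask = m)
}
pool2_bwd <- function(dy, cache) {
  r2 <- nrow(dy)
  dx <- matrix(0, 2 * r2, ncol(dy))
  odd <- seq(1, 2 * r2, by = 2)
  dx[odd, ] <- dy * cache$mask
  dx[odd + 1, ] <- dy * (1 - cache$mask)
  dx
}
upsample2_fwd <- function(x) {
  r <- nrow(x)
  y <- matrix(0, 2 * r, ncol(x))
  odd <- seq(1, 2 * r, by = 2)
  y[odd, ] <- x
  y[odd + 1, ] <- x
  y
}
upsample2_bwd <- function(dy) {
  r2 <- nrow(dy)
  odd <- seq(1, r2, by = 2)
  dy[odd, , drop = FALSE] + dy[odd + 1, , drop = FALSE]
}

# sinusoidal positional encoding [T x C]
positional_encoding <- function(T, C) {
  pos <- seq_len(T) - 1
  i <- seq_len(C) - 1
  ang <- outer(pos, 1 / 10000^((i %/% 2) * 2 / C))
  pe <- matrix(0, T, C)
  even <- seq(1, C, by = 2)
  pe[, even] <- sin(ang[, even, drop = FALSE])
  if (C > 1) {
    odd <- seq(2, C, by = 2)
    pe[, odd] <- cos(ang[, odd, drop = FALSE])
  }
  pe
}

# multihead self-attention with residual connection ---------------------------
mhsa_fwd <- function(x, p, bsz, tlen, heads) {
  C <- ncol(x)
  dh <- C %/% heads
  caches <- vector("list", bsz)
  y <- x
  for (b in seq_len(bsz)) {
    rows <- (b - 1) * tlen + seq_len(tlen)
    xb <- x[rows, , drop = FALSE]
    Q <- xb %*% p$Wq; K <- xb %*% p$Wk; V <- xb %*% p$Wv
    O <- matrix(0, tlen, C)
    A <- vector("list", heads)
    for (h in seq_len(heads)) {
      cols <- (h - 1) * dh + seq_len(dh)
      S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
      S <- S - S[cbind(seq_len(tlen), max.col(S, ties.method = "first"))]
      E <- exp(S)
      A[[h]] <- E / rowSums(E)
      O[, cols] <- A[[h]] %*% V[, cols, drop = FALSE]
    }
    out <- O %*% p$Wo
    out <- out + rep(p$bo, each = tlen)
    y[rows, ] <- xb + out
    caches[[b]] <- list(xb = xb, Q = Q, K = K, V = V, A = A, O = O)
  }
  list(y = y, caches = caches)
}
mhsa_bwd <- function(dy, cache, p, bsz, tlen, heads) {
  C <- ncol(dy)
  dh <- C %/% heads
  dx <- dy
  g <- list(Wq = 0 * p$Wq, Wk = 0 * p$Wk, Wv = 0 * p$Wv,
            Wo = 0 * p$Wo, bo = 0 * p$bo)
  for (b in seq_len(bsz)) {
    rows <- (b - 1) * tlen + seq_len(tlen)
    cb <- cache$caches[[b]]
    dyb <- dy[rows, , drop = FALSE]
    g$bo <- g$bo + colSums(dyb)
    g$Wo <- g$Wo + crossprod(cb$O, dyb)
    dO <- dyb %*% t(p$Wo)
    dQ <- matrix(0, tlen, C); dK <- dQ; dV <- dQ
    for (h in seq_len(heads)) {
      cols <- (h - 1) * dh + seq_len(dh)
      A <- cb$A[[h]]
      dOh <- dO[, cols, drop = FALSE]
      dA <- tcrossprod(dOh, cb$V[, cols, drop = FALSE])
      dV[, cols] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A))
      dQ[, cols] <- dS %*% cb$K[, cols, drop = FALSE] / sqrt(dh)
      dK[, cols] <- crossprod(dS, cb$Q[, cols, drop = FALSE]) / sqrt(dh)
    }
    g$Wq <- g$Wq + crossprod(cb$xb, dQ)
    g$Wk <- g$Wk + crossprod(cb$xb, dK)
    g$Wv <- g$Wv + crossprod(cb$xb, dV)
    dx[rows, ] <- dyb + dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  }
  c(list(dx = dx), g)
}
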