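# Low-level layer operations on (H, W, C, N) activation arrays.
#
# Convolutions are evaluated as im2col + GEMM so the heavy lifting is a
# single matrix product; backward passes reuse the cached column matrix.
# "same" padding follows the ceil(H/stride) convention with the smaller
# half of the padding at the top/left.

pad_hw <- function(h, k, s, padding) {
  if (padding == "valid") return(c(0L, 0L, (h - k) %/% s + 1L))
  oh <- ceiling(h / s)
  tot <- max((oh - 1L) * s + k - h, 0L)
  c(tot %/% 2L, tot - tot %/% 2L, oh)
}

pad_array <- function(x, pt, pb, pl, pr, value = 0) {
  if (pt + pb + pl + pr == 0L) return(x)
  d <- dim(x)
  xp <- array(value, dim = c(d[1] + pt + pb, d[2] + pl + pr, d[3], d[4]))
  xp[pt + seq_len(d[1]), pl + seq_len(d[2]), , ] <- x
  xp
}

# column matrix of all receptive fields: (oh*ow*N) x (kh*kw*C)
im2col <- function(xp, kh, kw, s, oh, ow) {
  d <- dim(xp)
  C <- d[3]; N <- d[4]
  cols <- array(0, dim = c(oh, ow, kh * kw * C, N))
  ys <- seq.int(1L, by = s, length.out = oh)
  xs <- seq.int(1L, by = s, length.out = ow)
  for (j in seq_len(kw)) for (i in seq_len(kh)) {
    slot <- ((j - 1L) * kh + (i - 1L)) * C + seq_len(C)
    cols[, , slot, ] <- xp[ys + i - 1L, xs + j - 1L, , , drop = FALSE]
  }
  matrix(aperm(cols, c(1L, 2L, 4L, 3L)), nrow = oh * ow * N)
}

# scatter-add of column gradients back onto the padded input
col2im <- function(dXmat, dims_p, kh, kw, s, oh, ow) {
  C <- dims_p[3]; N <- dims_p[4]
  dcols <- aperm(array(dXmat, dim = c(oh, ow, N, kh * kw * C)), c(1L, 2L, 4L, 3L))
  dxp <- array(0, dim = dims_p)
  ys <- seq.int(1L, by = s, length.out = oh)
  xs <- seq.int(1L, by = s, length.out = ow)
  for (j in seq_len(kw)) for (i in seq_len(kh)) {
    slot <- ((j - 1L) * kh + (i - 1L)) * C + seq_len(C)
    dxp[ys + i - 1L, xs + j - 1L, , ] <-
      dxp[ys + i - 1L, xs + j - 1L, , , drop = FALSE] +
      dcols[, , slot, , drop = FALSE]
  }
  dxp
}

conv_fwd <- function(x, W, b, stride, padding) {
  d <- dim(x); kd <- dim(W)
  ph <- pad_hw(d[1], kd[1], stride, padding)
  pw <- pad_hw(d[2], kd[2], stride, padding)
  xp <- pad_array(x, ph[1], ph[2], pw[1], pw[2])
  oh <- ph[3]; ow <- pw[3]
  X <- im2col(xp, kd[1], kd[2], stride, oh, ow)
  Wm <- matrix(aperm(W, c(3L, 1L, 2L, 4L)), ncol = kd[4])
  Y <- X %*% Wm
  if (!is.null(b)) Y <- sweep(Y, 2L, b, "+")
  out <- aperm(array(Y, dim = c(oh, ow, d[4], kd[4])), c(1L, 2L, 4L, 3L))
  list(out = out, X = X, dims_p = dim(xp),
       pads = c(ph[1], ph[2], pw[1], pw[2]), oh = oh, ow = ow)
}

conv_bwd <- function(dout, cache, W, has_bias, stride, need_dx = TRUE) {
  kd <- dim(W)
  dY <- matrix(aperm(dout, c(1L, 2L, 4L, 3L)), ncol = kd[4])
  dWm <- crossprod(cache$X, dY)
  dW <- aperm(array(dWm, dim = c(kd[3], kd[1], kd[2], kd[4])), c(2L, 3L, 1L, 4L))
  db <- if (has_bias) colSums(dY) else NULL
  dx <- NULL
  if (need_dx) {
    Wm <- matrix(aperm(W, c(3L, 1L, 2L, 4L)), ncol = kd[4])
    dxp <- col2im(tcrossprod(dY, Wm), cache$dims_p, kd[1], kd[2], stride,
                  cache$oh, cache$ow)
    p <- cache$pads
    dx <- dxp[p[1] + seq_len(cache$dims_p[1] - p[1] - p[2]),
              p[3] + seq_len(cache$dims_p[2] - p[3] - p[4]), , , drop = FALSE]
  }
  list(dx = dx, dW = dW, db = db)
}

maxpool_fwd <- function(x, k, stride, padding) {
  d <- dim(x)
  ph <- pad_hw(d[1], k, stride, padding)
  pw <- pad_hw(d[2], k, stride, padding)
  xp <- pad_array(x, ph[1], ph[2], pw[1], pw[2], value = -Inf)
  oh <- ph[3]; ow <- pw[3]
  ys <- seq.int(1L, by = stride, length.out = oh)
  xs <- seq.int(1L, by = stride, length.out = ow)
  best <- array(-Inf, dim = c(oh, ow, d[3], d[4]))
  arg <- array(0L, dim = c(oh, ow, d[3], d[4]))
  idx <- 0L
  for (j in seq_len(k)) for (i in seq_len(k)) {
    idx <- idx + 1L
    s <- xp[ys + i - 1L, xs + j - 1L, , , drop = FALSE]
    upd <- s > best
    best[upd] <- s[upd]
    arg[upd] <- idx
  }
  list(out = best, arg = arg, dims_p = dim(xp),
       pads = c(ph[1], ph[2], pw[1], pw[2]), oh = oh, ow = ow)
}

maxpool_bwd <- function(dout, cache, k, stride) {
  dxp <- array(0, dim = cache$dims_p)
  ys <- seq.int(1L, by = stride, length.out = cache$oh)
  xs <- seq.int(1L, by = stride, length.out = cache$ow)
  idx <- 0L
  for (j in seq_len(k)) for (i in seq_len(k)) {
    idx <- idx + 1L
    m <- dout * (cache$arg == idx)
    dxp[ys + i - 1L, xs + j - 1L, , ] <-
      dxp[ys + i - 1L, xs + j - 1L, , , drop = FALSE] + m
  }
  p <- cache$pads
  dxp[p[1] + seq_len(cache$dims_p[1] - p[1] - p[2]),
      p[3] + seq_len(cache$dims_p[2] - p[3] - p[4]), , , drop = FALSE]
}

BN_EPS <- 1e-5

bn_fwd <- function(x, gamma, beta, mov_mean, mov_var, training) {
  d <- dim(x)
  if (training) {
    mu <- channel_mean(x)
    xc <- x - bcast_ch(mu, d)
    v <- channel_sum(xc * xc) / (d[1] * d[2] * d[4])
  } else {
    mu <- mov_mean; v <- mov_var
    xc <- x - bcast_ch(mu, d)
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  xhat <- xc * bcast_ch(invstd, d)
  out <- xhat * bcast_ch(gamma, d) + bcast_ch(beta, d)
  list(out = out, xhat = xhat, invstd = invstd, batch_mean = mu, batch_var = v)
}

bn_bwd <- function(dout, cache, gamma) {
  d <- dim(dout)
  m <- d[1] * d[2] * d[4]
  dgamma <- channel_sum(dout * cache$xhat)
  dbeta <- channel_sum(dout)
  dxhat <- dout * bcast_ch(gamma, d)
  s1 <- channel_sum(dxhat)
  s2 <- channel_sum(dxhat * cache$xhat)
  dx <- bcast_ch(cache$invstd / m, d) *
    (m * dxhat - bcast_ch(s1, d) - cache$xhat * bcast_ch(s2, d))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

dense_fwd <- function(x, W, b) {
  # x: (features, N); W: (out, features)
  list(out = sweep(W %*% x, 1L, b, "+"), x = x)
}

dense_bwd <- function(dout, cache, W) {
  list(dx = crossprod(W, dout), dW = tcrossprod(dout, cache$x), db = rowSums(dout))
}

softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max), "-")
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

# mean cross-entropy over columns; y is (N x C) one-hot/soft
cross_entropy <- function(p, y) {
  -mean(rowSums(y * log(pmax(t(p), 1e-12))))
}
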