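# Neural-network primitives on base-R matrix operations.
#
# Activations are arrays dim (H, W, C, N). Convolutions are computed by
# im2col gathers followed by one BLAS matrix product; the gather/scatter
# index tables are precomputed per layer geometry. Padding follows the
# "same"-style rule out = ceiling(in / stride), with the excess padded
# asymmetrically (less on the top/left) — the convention under which the
# ECM network's published activation-shape chain is reproduced exactly.

conv_geometry <- function(in_h, in_w, in_c, kh, kw, sh, sw) {
  out_h <- ceiling(in_h / sh)
  out_w <- ceiling(in_w / sw)
  pad_h <- max((out_h - 1L) * sh + kh - in_h, 0L)
  pad_w <- max((out_w - 1L) * sw + kw - in_w, 0L)
  pt <- pad_h %/% 2L
  pl <- pad_w %/% 2L
  p_h <- in_h + pad_h
  p_w <- in_w + pad_w
  P <- out_h * out_w
  K <- kh * kw * in_c
  oh <- rep(seq_len(out_h), times = out_w)              # p = oh + (ow-1)*out_h
  ow <- rep(seq_len(out_w), each = out_h)
  idx <- matrix(0L, P, K)
  k <- 0L
  for (c in seq_len(in_c)) {
    for (kwi in seq_len(kw)) {
      for (khi in seq_len(kh)) {
        k <- k + 1L
        h <- (oh - 1L) * sh + khi
        w <- (ow - 1L) * sw + kwi
        idx[, k] <- h + (w - 1L) * p_h + (c - 1L) * p_h * p_w
      }
    }
  }
  # reorder columns so k = khi + (khi over kh) etc.; ordering only needs to be
  # consistent between idx and the weight layout, which it is by construction
  fh <- rep(seq_len(in_h), times = in_w * in_c) + pt
  fw <- rep(rep(seq_len(in_w), each = in_h), times = in_c) + pl
  fc <- rep(seq_len(in_c), each = in_h * in_w)
  fill_idx <- fh + (fw - 1L) * p_h + (fc - 1L) * p_h * p_w
  list(in_h = in_h, in_w = in_w, in_c = in_c, kh = kh, kw = kw,
       sh = sh, sw = sw, out_h = out_h, out_w = out_w,
       p_h = p_h, p_w = p_w, P = P, K = K,
       idx = idx, fill_idx = fill_idx)
}

# im2col over a batch: returns (N*P) x K matrix, rows ordered image-major
# (row (n-1)*P + p holds patch p of image n)
im2col <- function(x, g, pad_value = 0) {
  n <- dim(x)[4]
  dim(x) <- c(g$in_h * g$in_w * g$in_c, n)
  pv <- cpp_pad_batch(x, g$fill_idx, g$p_h * g$p_w * g$in_c, pad_value)
  cpp_im2col(pv, g$idx)
}

# scatter-add of per-patch values back onto the (unpadded) input: inverse of
# im2col with accumulation over overlapping patches
col2im <- function(dcols, g, n) {
  dpad <- cpp_col2im(dcols, g$idx, g$p_h * g$p_w * g$in_c, n)
  array(cpp_unpad_batch(dpad, g$fill_idx), c(g$in_h, g$in_w, g$in_c, n))
}

cols_to_array <- function(z, g, n, out_c) {
  a <- array(z, c(g$P, n, out_c))
  a <- aperm(a, c(1L, 3L, 2L))
  dim(a) <- c(g$out_h, g$out_w, out_c, n)
  a
}

array_to_cols <- function(a, g, n, out_c) {
  dim(a) <- c(g$P, out_c, n)
  a <- aperm(a, c(1L, 3L, 2L))
  dim(a) <- c(g$P * n, out_c)
  a
}

conv_forward <- function(layer, x, keep_cache = TRUE) {
  g <- layer$geom
  n <- dim(x)[4]
  cols <- im2col(x, g)
  z <- cols %*% layer$W
  z <- z + rep(layer$b, each = nrow(z))
  out <- cols_to_array(z, g, n, ncol(layer$W))
  cache <- if (keep_cache) list(cols = cols, n = n) else NULL
  list(out = out, cache = cache)
}

conv_backward <- function(layer, dout, cache) {
  g <- layer$geom
  dz <- array_to_cols(dout, g, cache$n, ncol(layer$W))
  dW <- crossprod(cache$cols, dz)
  db <- colSums(dz)
  dcols <- tcrossprod(dz, layer$W)
  dx <- col2im(dcols, g, cache$n)
  list(dx = dx, dW = dW, db = db)
}

pool_geometry <- function(in_h, in_w, kh, kw, sh, sw) {
  conv_geometry(in_h, in_w, 1L, kh, kw, sh, sw)
}

pool_forward <- function(layer, x, keep_cache = TRUE) {
  g <- layer$geom
  d <- dim(x)
  cn <- d[3] * d[4]
  dim(x) <- c(d[1] * d[2], cn)
  pv <- cpp_pad_batch(x, g$fill_idx, g$p_h * g$p_w, -Inf)
  r <- cpp_pool_forward(pv, g$idx)
  out <- r$best
  dim(out) <- c(g$out_h, g$out_w, d[3], d[4])
  cache <- if (keep_cache) list(argk = r$argk, in_dim = d) else NULL
  list(out = out, cache = cache)
}

# route values at pooled positions back to their argmax inputs (used both for
# gradients and winner-take-all relevance redistribution)
pool_backward <- function(layer, dout, cache) {
  g <- layer$geom
  d <- cache$in_dim
  cn <- d[3] * d[4]
  dim(dout) <- c(g$P, cn)
  dpad <- cpp_pool_backward(dout, cache$argk, g$idx, g$p_h * g$p_w)
  dx <- cpp_unpad_batch(dpad, g$fill_idx)
  dim(dx) <- d
  list(dx = dx)
}

bn_forward <- function(layer, x, mode, keep_cache = TRUE, eps = 1e-5,
                       momentum = 0.1) {
  d <- dim(x)
  C <- d[3]
  xm <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(xm) <- c(d[1] * d[2] * d[4], C)
  if (mode == "train") {
    mu <- colMeans(xm)
    ctr <- sweep(xm, 2L, mu)
    v <- colMeans(ctr^2)
    layer$running_mean <- (1 - momentum) * layer$running_mean + momentum * mu
    layer$running_var <- (1 - momentum) * layer$running_var + momentum * v
  } else {
    mu <- layer$running_mean
    v <- layer$running_var
    ctr <- sweep(xm, 2L, mu)
  }
  inv_std <- 1 / sqrt(v + eps)
  xhat <- sweep(ctr, 2L, inv_std, `*`)
  ym <- sweep(sweep(xhat, 2L, layer$gamma, `*`), 2L, layer$beta, `+`)
  y <- array(ym, c(d[1], d[2], d[4], C))
  y <- aperm(y, c(1L, 2L, 4L, 3L))
  cache <- if (keep_cache) list(xhat = xhat, inv_std = inv_std, d = d) else NULL
  list(out = y, cache = cache, layer = layer)
}

bn_backward <- function(layer, dout, cache) {
  d <- cache$d
  C <- d[3]
  dym <- aperm(dout, c(1L, 2L, 4L, 3L))
  dim(dym) <- c(d[1] * d[2] * d[4], C)
  m <- nrow(dym)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2L, layer$gamma, `*`)
  t1 <- sweep(dxhat, 2L, colSums(dxhat) / m)
  t2 <- sweep(cache$xhat, 2L, colSums(dxhat * cache$xhat) / m, `*`)
  dxm <- sweep(t1 - t2, 2L, cache$inv_std, `*`)
  dx <- array(dxm, c(d[1], d[2], d[4], C))
  dx <- aperm(dx, c(1L, 2L, 4L, 3L))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x, keep_cache = TRUE) {
  out <- pmax(x, 0)
  list(out = out, cache = if (keep_cache) list(mask = x > 0) else NULL)
}

fc_forward <- function(layer, x, keep_cache = TRUE) {
  d <- dim(x)
  n <- d[4]
  xm <- x
  dim(xm) <- c(prod(d[1:3]), n)
  z <- layer$W %*% xm + layer$b
  list(out = z, cache = if (keep_cache) list(xm = xm, in_dim = d) else NULL)
}

fc_backward <- function(layer, dz, cache) {
  dW <- tcrossprod(dz, cache$xm)
  db <- rowSums(dz)
  dxm <- crossprod(layer$W, dz)
  dx <- array(dxm, cache$in_dim)
  list(dx = dx, dW = dW, db = db)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), `/`)
}
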