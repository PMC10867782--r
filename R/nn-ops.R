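# Differentiable network operations built on the autodiff tape and the
# compiled convolution kernels.

# ---- convolutions ----------------------------------------------------------

# Standard 2-D convolution, zero padding. x: H x W x Cin node; W: kh x kw x
# Cin x Cout parameter; b: length-Cout parameter or NULL.
ag_conv2d <- function(x, W, b = NULL, stride = 1L, pad = 0L) {
  x <- as_node(x)
  xv <- x$value; Wv <- W$value
  out <- cpp_conv2d_forward(xv, Wv, as.integer(stride), as.integer(pad))
  od <- dim(out)
  if (!is.null(b)) out <- out + rep(b$value, each = od[1] * od[2])
  parents <- if (is.null(b)) list(x, W) else list(x, W, b)
  ag_op(out, parents, function(g) {
    if (is.null(dim(g))) dim(g) <- od
    bk <- cpp_conv2d_backward(xv, Wv, g, as.integer(stride), as.integer(pad))
    gb <- if (is.null(b)) NULL else colSums(matrix(g, ncol = od[3]))
    if (is.null(b)) list(bk$gx, bk$gW) else list(bk$gx, bk$gW, gb)
  })
}

# Deformable convolution: sampling taps displaced by the (learned) offset
# field, bilinear interpolation, zero outside bounds. Gradients flow to the
# input, the weights, the bias and the offsets.
ag_deform_conv <- function(x, W, b, offsets, stride = 1L, pad = 0L) {
  x <- as_node(x); offsets <- as_node(offsets)
  xv <- x$value; Wv <- W$value; ov <- offsets$value
  wd <- dim(Wv); od <- dim(ov)
  if (od[3] != 2L * wd[1] * wd[2]) stop("offset channels must equal 2 * kernel taps")
  out <- cpp_deform_conv_forward(xv, Wv, ov, as.integer(stride), as.integer(pad))
  od <- dim(out)
  if (!is.null(b)) out <- out + rep(b$value, each = od[1] * od[2])
  parents <- if (is.null(b)) list(x, W, offsets) else list(x, W, b, offsets)
  ag_op(out, parents, function(g) {
    if (is.null(dim(g))) dim(g) <- od
    bk <- cpp_deform_conv_backward(xv, Wv, ov, g, as.integer(stride),
                                   as.integer(pad))
    if (is.null(b)) {
      list(bk$gx, bk$gW, bk$goff)
    } else {
      gb <- colSums(matrix(g, ncol = od[3]))
      list(bk$gx, bk$gW, gb, bk$goff)
    }
  })
}

# Fractionally-strided (transposed) convolution, upsampling factor 2:
# zero-dilate then convolve with a 4x4 kernel at stride 1, pad 2, which
# doubles the spatial resolution exactly.
ag_conv_transpose2 <- function(x, W, b = NULL) {
  ag_conv2d(ag_dilate2(x), W, b, stride = 1L, pad = 2L)
}

# ---- normalization ---------------------------------------------------------

# Batch normalization over the spatial extent of one sample (per-channel
# statistics), with learned gain/offset.
ag_batchnorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_node(x)
  xv <- x$value
  d <- dim(xv); n <- d[1] * d[2]
  xm <- matrix(xv, nrow = n)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  va <- colSums(xc^2) / n
  sdv <- sqrt(va + eps)
  xhat <- sweep(xc, 2, sdv, "/")
  y <- sweep(xhat, 2, gamma$value, "*")
  y <- sweep(y, 2, beta$value, "+")
  out <- array(y, dim = d)
  ag_op(out, list(x, gamma, beta), function(g) {
    gm <- matrix(g, nrow = n)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    dxhat <- sweep(gm, 2, gamma$value, "*")
    # standard batchnorm backward over the n spatial positions
    t1 <- sweep(dxhat, 2, colMeans(dxhat))
    t2 <- sweep(xhat, 2, colMeans(dxhat * xhat), "*")
    dx <- sweep(t1 - t2, 2, sdv, "/")
    list(array(dx, dim = d), dgamma, dbeta)
  })
}

# Parameter-free per-channel standardization over spatial positions (the
# normalization stage inside a SPADE block).
ag_standardize <- function(x, eps = 1e-5) {
  x <- as_node(x)
  xv <- x$value
  d <- dim(xv); n <- d[1] * d[2]
  xm <- matrix(xv, nrow = n)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  sdv <- sqrt(colSums(xc^2) / n + eps)
  xhat <- sweep(xc, 2, sdv, "/")
  ag_op(array(xhat, dim = d), list(x), function(g) {
    gm <- matrix(g, nrow = n)
    t1 <- sweep(gm, 2, colMeans(gm))
    t2 <- sweep(xhat, 2, colMeans(gm * xhat), "*")
    dx <- sweep(t1 - t2, 2, sdv, "/")
    list(array(dx, dim = d))
  })
}

# ---- pooling and spatial reductions ---------------------------------------

# Non-overlapping average pooling by integer factor f.
ag_avgpool <- function(x, f) {
  x <- as_node(x)
  d <- dim(x$value)
  if (d[1] %% f != 0 || d[2] %% f != 0) stop("size not divisible by pool factor")
  Ho <- d[1] %/% f; Wo <- d[2] %/% f
  a <- array(x$value, dim = c(f, Ho, f, Wo, d[3]))
  out <- apply(a, c(2, 4, 5), mean)
  dim(out) <- c(Ho, Wo, d[3])
  ag_op(out, list(x), function(g) {
    # every position of a pooling cell receives g / f^2
    gb <- array(g / f^2, dim = c(Ho, Wo, d[3]))
    ge <- array(0, dim = c(f, Ho, f, Wo, d[3]))
    for (i in seq_len(f)) for (j in seq_len(f)) ge[i, , j, , ] <- gb
    list(array(ge, dim = d))
  })
}

# Global average pooling to a per-channel vector.
ag_gap <- function(x) {
  x <- as_node(x)
  d <- dim(x$value); n <- d[1] * d[2]
  ag_op(colMeans(matrix(x$value, nrow = n)), list(x), function(g) {
    list(array(rep(g / n, each = n), dim = d))
  })
}

# Global max pooling to a per-channel vector.
ag_gmp <- function(x) {
  x <- as_node(x)
  d <- dim(x$value); n <- d[1] * d[2]
  xm <- matrix(x$value, nrow = n)
  idx <- apply(xm, 2, which.max)
  ag_op(xm[cbind(idx, seq_len(d[3]))], list(x), function(g) {
    gr <- matrix(0, nrow = n, ncol = d[3])
    gr[cbind(idx, seq_len(d[3]))] <- g
    list(array(gr, dim = d))
  })
}

# Mean over the channel axis -> H x W x 1 (spatial attention input).
ag_channel_mean <- function(x) {
  x <- as_node(x)
  d <- dim(x$value)
  xm <- matrix(x$value, ncol = d[3])
  ag_op(array(rowMeans(xm), dim = c(d[1], d[2], 1L)), list(x), function(g) {
    list(array(rep(as.vector(g) / d[3], d[3]), dim = d))
  })
}

# Max over the channel axis -> H x W x 1; ties broken by the first channel
# for determinism.
ag_channel_max <- function(x) {
  x <- as_node(x)
  d <- dim(x$value)
  xm <- matrix(x$value, ncol = d[3])
  j <- max.col(xm, ties.method = "first")
  n <- nrow(xm)
  ag_op(array(xm[cbind(seq_len(n), j)], dim = c(d[1], d[2], 1L)),
        list(x), function(g) {
    gr <- matrix(0, nrow = n, ncol = d[3])
    gr[cbind(seq_len(n), j)] <- as.vector(g)
    list(array(gr, dim = d))
  })
}

# Multiply an H x W x C map by an H x W x 1 spatial mask.
ag_mul_mask <- function(x, m) {
  x <- as_node(x); m <- as_node(m)
  d <- dim(x$value)
  mv <- as.vector(m$value)
  xv <- x$value
  out <- array(as.vector(xv) * rep(mv, d[3]), dim = d)
  ag_op(out, list(x, m), function(g) {
    gx <- array(as.vector(g) * rep(mv, d[3]), dim = d)
    gm <- rowSums(matrix(as.vector(g) * as.vector(xv), ncol = d[3]))
    list(gx, array(gm, dim = c(d[1], d[2], 1L)))
  })
}

# ---- dense / vector ops ----------------------------------------------------

# Fully-connected layer on a vector: y = W v + b, W is n_out x n_in.
ag_dense <- function(v, W, b) {
  v <- as_node(v)
  vv <- v$value; Wv <- W$value
  ag_op(as.vector(Wv %*% vv) + b$value, list(v, W, b), function(g) {
    list(as.vector(crossprod(Wv, g)), outer(g, vv), g)
  })
}

ag_softmax <- function(v) {
  v <- as_node(v)
  e <- exp(v$value - max(v$value))
  y <- e / sum(e)
  ag_op(y, list(v), function(g) {
    list(y * (g - sum(g * y)))
  })
}

ag_add_vec <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ag_op(a$value + b$value, list(a, b), function(g) list(g, g))
}

# Weighted composition of images by scalar attention weights (content
# revisor output): out = sum_i w[i] * imgs[[i]].
ag_attention_compose <- function(imgs, w) {
  imgs <- lapply(imgs, as_node); w <- as_node(w)
  wv <- w$value
  vals <- lapply(imgs, function(n) n$value)
  out <- vals[[1]] * wv[1]
  for (i in seq_along(vals)[-1]) out <- out + vals[[i]] * wv[i]
  ag_op(out, c(imgs, list(w)), function(g) {
    gs <- lapply(seq_along(vals), function(i) g * wv[i])
    gw <- vapply(vals, function(v) sum(g * v), 0)
    c(gs, list(gw))
  })
}

# ---- fixed-kernel blur (differentiable in the image) -----------------------

# Convolution with a fixed (constant) kernel array: no weight gradient.
ag_conv2d_const <- function(x, Warr, stride = 1L, pad = 0L) {
  x <- as_node(x)
  xv <- x$value
  out <- cpp_conv2d_forward(xv, Warr, as.integer(stride), as.integer(pad))
  od <- dim(out)
  ag_op(out, list(x), function(g) {
    if (is.null(dim(g))) dim(g) <- od
    bk <- cpp_conv2d_backward(xv, Warr, g, as.integer(stride),
                              as.integer(pad), FALSE)
    list(bk$gx)
  })
}

# Per-channel 2-D convolution with a fixed normalized kernel and symmetric
# (reflect) padding; linear in the input. When the kernel is separable the
# two 1-D passes are used (`g1` is the 1-D factor); the result equals the
# full 2-D convolution with outer(g1, g1).
ag_blur <- function(x, kernel, g1 = NULL) {
  x <- as_node(x)
  k <- dim(kernel)[1]
  r <- (k - 1L) %/% 2L
  xp <- ag_pad_reflect(x, r)
  d <- dim(xp$value)
  if (!is.null(g1)) {
    Wv <- array(0, dim = c(k, 1L, d[3], d[3]))
    for (c in seq_len(d[3])) Wv[, 1L, c, c] <- g1
    Wh <- array(0, dim = c(1L, k, d[3], d[3]))
    for (c in seq_len(d[3])) Wh[1L, , c, c] <- g1
    return(ag_conv2d_const(ag_conv2d_const(xp, Wv), Wh))
  }
  Wk <- array(0, dim = c(k, k, d[3], d[3]))
  for (c in seq_len(d[3])) Wk[, , c, c] <- kernel
  ag_conv2d_const(xp, Wk)
}
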