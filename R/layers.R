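# Layer constructors (Xavier initialization) and parameter bookkeeping.

xavier_weights <- function(kh, kw, cin, cout) {
  a <- sqrt(6 / (kh * kw * cin + kh * kw * cout))
  array(runif(kh * kw * cin * cout, -a, a), dim = c(kh, kw, cin, cout))
}

conv_layer <- function(kh, kw, cin, cout, zero_init = FALSE) {
  W <- if (zero_init) array(0, dim = c(kh, kw, cin, cout))
       else xavier_weights(kh, kw, cin, cout)
  list(W = ag_param(W), b = ag_param(numeric(cout)),
       kh = kh, kw = kw, cin = cin, cout = cout)
}

bn_layer <- function(ch) {
  list(gamma = ag_param(rep(1, ch)), beta = ag_param(numeric(ch)))
}

dense_layer <- function(nin, nout) {
  a <- sqrt(6 / (nin + nout))
  list(W = ag_param(matrix(runif(nin * nout, -a, a), nout, nin)),
       b = ag_param(numeric(nout)))
}

# Deformable convolution block: offset-prediction convolution (zero-
# initialized so training starts at the plain-convolution reduction case),
# deformable convolution, batch normalization, optional LeakyReLU.
defc_block <- function(k, cin, cout) {
  list(off = conv_layer(k, k, cin, 2L * k * k, zero_init = TRUE),
       conv = conv_layer(k, k, cin, cout),
       bn = bn_layer(cout), k = k)
}

fw_defc <- function(blk, x, stride, pad, act = TRUE) {
  off <- ag_conv2d(x, blk$off$W, blk$off$b, stride = stride, pad = pad)
  h <- ag_deform_conv(x, blk$conv$W, blk$conv$b, off, stride = stride, pad = pad)
  h <- ag_batchnorm(h, blk$bn$gamma, blk$bn$beta)
  if (act) ag_leaky_relu(h) else h
}

# Downsampling deformable residual block: two deformable convolution blocks
# (first strided) with a strided 1x1 shortcut.
defres_block <- function(cin, cout) {
  list(d1 = defc_block(3L, cin, cout),
       d2 = defc_block(3L, cout, cout),
       sc = conv_layer(1L, 1L, cin, cout))
}

fw_defres <- function(blk, x) {
  h <- fw_defc(blk$d1, x, stride = 2L, pad = 1L, act = TRUE)
  h <- fw_defc(blk$d2, h, stride = 1L, pad = 1L, act = FALSE)
  s <- ag_conv2d(x, blk$sc$W, blk$sc$b, stride = 2L, pad = 0L)
  ag_leaky_relu(ag_add(h, s))
}

# Standard residual block: conv-BN-ReLU-conv-BN plus identity shortcut (no
# activation after the sum so zero weights give the identity map).
res_block <- function(ch) {
  list(c1 = conv_layer(3L, 3L, ch, ch), n1 = bn_layer(ch),
       c2 = conv_layer(3L, 3L, ch, ch), n2 = bn_layer(ch))
}

fw_res <- function(blk, x) {
  h <- ag_conv2d(x, blk$c1$W, blk$c1$b, stride = 1L, pad = 1L)
  h <- ag_relu(ag_batchnorm(h, blk$n1$gamma, blk$n1$beta))
  h <- ag_conv2d(h, blk$c2$W, blk$c2$b, stride = 1L, pad = 1L)
  h <- ag_batchnorm(h, blk$n2$gamma, blk$n2$beta)
  ag_add(x, h)
}

# Spatial attention: channel-wise mean and max maps -> 7x7 convolution ->
# sigmoid mask in (0,1) -> elementwise product with the input.
sa_module <- function() {
  list(conv = conv_layer(7L, 7L, 2L, 1L))
}

fw_sa <- function(blk, x) {
  m <- ag_concat_c(list(ag_channel_mean(x), ag_channel_max(x)))
  mask <- ag_sigmoid(ag_conv2d(m, blk$conv$W, blk$conv$b, stride = 1L, pad = 3L))
  list(out = ag_mul_mask(x, mask), mask = mask)
}

# SPADE block: parameter-free per-channel standardization, spatially-variant
# modulation (1 + gamma) * xhat + beta predicted from the concatenated skip
# features and resized raw image, then activation and convolution.
spade_block <- function(ch, cond_ch, hidden = ch) {
  list(m1 = conv_layer(3L, 3L, cond_ch, hidden),
       mg = conv_layer(3L, 3L, hidden, ch),
       mb = conv_layer(3L, 3L, hidden, ch),
       out = conv_layer(3L, 3L, ch, ch))
}

fw_spade <- function(blk, h, skip, raw) {
  xhat <- ag_standardize(h)
  cond <- ag_concat_c(list(skip, raw))
  hm <- ag_relu(ag_conv2d(cond, blk$m1$W, blk$m1$b, stride = 1L, pad = 1L))
  gam <- ag_conv2d(hm, blk$mg$W, blk$mg$b, stride = 1L, pad = 1L)
  bet <- ag_conv2d(hm, blk$mb$W, blk$mb$b, stride = 1L, pad = 1L)
  denorm <- ag_add(ag_add(xhat, ag_mul(xhat, gam)), bet)
  out <- ag_conv2d(ag_relu(denorm), blk$out$W, blk$out$b, stride = 1L, pad = 1L)
  list(out = out, denorm = denorm, normalized = xhat)
}

# SPADE residual block: two SPADE blocks with a shortcut connection.
spade_res_block <- function(ch, cond_ch) {
  list(s1 = spade_block(ch, cond_ch), s2 = spade_block(ch, cond_ch))
}

fw_spade_res <- function(blk, h, skip, raw) {
  a <- fw_spade(blk$s1, h, skip, raw)$out
  b <- fw_spade(blk$s2, a, skip, raw)$out
  ag_add(h, b)
}

# Transposed-convolution upsampling layer (factor 2, 4x4 kernel).
upconv_layer <- function(cin, cout) conv_layer(4L, 4L, cin, cout)

fw_upconv <- function(blk, x) ag_conv_transpose2(x, blk$W, blk$b)

#' Collect the trainable parameter nodes of a model
#' @param x Nested list of layers.
#' @return Flat list of parameter `ag_node`s.
#' @keywords internal
#' @export
collect_params <- function(x) {
  if (inherits(x, "ag_node")) {
    if (isTRUE(x$is_param)) return(list(x)) else return(list())
  }
  if (is.list(x)) return(do.call(c, lapply(x, collect_params)))
  list()
}

n_parameters <- function(x) {
  sum(vapply(collect_params(x), function(p) length(p$value), 0))
}
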