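# The three-part generator: a local branch with a deformable-convolution
# encoder and SPADE decoder operating on the 128 px nodule ROI, a global
# branch with spatial attention operating on the full 256 px image, feature
# fusion between the two at the bottleneck, and a content revisor that
# composes n-1 foreground content masks with the input background under
# softmax channel attention.

#' Network architecture configuration
#'
#' @param base_channels Channel width of the first stage (64 at full scale;
#'   8 in the desk-scale CPU profile).
#' @param n_downsamples_global,n_downsamples_local Number of stride-2 stages
#'   per branch.
#' @param n_resblocks Residual blocks at the bottleneck of each branch.
#' @param n_groups Content-revisor groups n (n-1 foreground masks plus the
#'   input background); must be >= 2.
#' @param roi_size Local-branch input resolution (pixels).
#' @param global_size Global-branch input resolution; must equal
#'   `2 * roi_size`.
#' @param seed Seed for weight initialization.
#' @return Object of class `network_config`.
#' @export
network_config <- function(base_channels = 64L, n_downsamples_global = 2L,
                           n_downsamples_local = 2L, n_resblocks = 9L,
                           n_groups = 4L, roi_size = 128L,
                           global_size = 256L, seed = 1L) {
  if (n_groups < 2L) stop("n_groups must be at least 2")
  if (global_size != 2L * roi_size) stop("global_size must equal 2 * roi_size")
  structure(list(base_channels = as.integer(base_channels),
                 n_downsamples_global = as.integer(n_downsamples_global),
                 n_downsamples_local = as.integer(n_downsamples_local),
                 n_resblocks = as.integer(n_resblocks),
                 n_groups = as.integer(n_groups),
                 roi_size = as.integer(roi_size),
                 global_size = as.integer(global_size),
                 seed = as.integer(seed)),
            class = "network_config")
}

#' Desk-scale network profile
#'
#' A narrow configuration (base 8 channels, 32 px ROI, 64 px global input)
#' whose full training step runs comfortably on one CPU.
#' @param seed Seed for weight initialization.
#' @return A [network_config()].
#' @export
desk_network_config <- function(seed = 42L) {
  network_config(base_channels = 8L, roi_size = 32L, global_size = 64L,
                 seed = seed)
}

#' Initialize the generator
#'
#' Builds all submodules (local branch, global branch, content revisor) with
#' Xavier-initialized weights; offset-prediction convolutions start at zero
#' so every deformable convolution begins as a plain convolution.
#'
#' @param config A [network_config()].
#' @return Object of class `tsegan_generator`.
#' @export
init_generator <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  b <- config$base_channels
  ndl <- config$n_downsamples_local
  ndg <- config$n_downsamples_global
  with_seed(config$seed, {
    local <- list(
      enc0 = defc_block(7L, 3L, b),
      down = lapply(seq_len(ndl), function(i)
        defres_block(b * 2L^(i - 1L), b * 2L^i)),
      fusion = lapply(seq_len(config$n_resblocks), function(i)
        res_block(b * 2L^ndl)),
      up = lapply(seq_len(ndl), function(i) {
        cin <- b * 2L^(ndl - i + 1L); cout <- b * 2L^(ndl - i)
        list(convT = upconv_layer(cin, cout),
             spade = spade_res_block(cout, cout + 3L))
      }),
      out = conv_layer(7L, 7L, b, 3L)
    )
    globalg <- list(
      enc0 = list(conv = conv_layer(7L, 7L, 3L, b), bn = bn_layer(b)),
      sa = sa_module(),
      down = lapply(seq_len(ndg), function(i)
        list(conv = conv_layer(3L, 3L, b * 2L^(i - 1L), b * 2L^i),
             bn = bn_layer(b * 2L^i))),
      proj = conv_layer(1L, 1L, b, b * 2L^ndg),
      fusion = lapply(seq_len(config$n_resblocks), function(i)
        res_block(b * 2L^ndg)),
      up = lapply(seq_len(ndg), function(i) {
        cin <- b * 2L^(ndg - i + 1L); cout <- b * 2L^(ndg - i)
        list(convT = upconv_layer(cin, cout),
             spade = spade_res_block(cout, cout + 3L))
      })
    )
    revisor <- list(
      content = lapply(seq_len(config$n_groups - 1L), function(i)
        conv_layer(3L, 3L, b, 3L)),
      attn_conv = conv_layer(3L, 3L, b, config$n_groups),
      fc = dense_layer(config$n_groups, config$n_groups)
    )
    structure(list(local = local, global = globalg, revisor = revisor,
                   config = config),
              class = "tsegan_generator")
  })
}

#' Encode a grayscale B-mode image as a normalized-Lab network tensor
#'
#' Grayscale has zero chroma, so the image embeds as L = 100 * gray with
#' a = b = 0, then the symmetric normalization is applied. This keeps the
#' content revisor's background term dimensionally consistent with the
#' color output.
#'
#' @param bmode H x W matrix in \[0, 1\].
#' @return H x W x 3 array in \[-1, 1\].
#' @export
bmode_to_input <- function(bmode) {
  lab <- array(0, dim = c(dim(bmode), 3L))
  lab[, , 1] <- 100 * bmode
  normalize_lab(lab)
}

# Elastogram (sRGB in [0,1]) -> normalized Lab tensor.
elastogram_to_target <- function(elastogram) {
  normalize_lab(rgb_to_lab(elastogram))
}

# Network output (normalized Lab in [-1,1]) -> sRGB in [0,1].
output_to_rgb <- function(x) {
  lab_to_rgb(denormalize_lab(ag_value(x)), quiet = TRUE)
}

# ---- local branch ----------------------------------------------------------

# Forward pass of the local generator on a normalized-Lab ROI node.
# Returns the tanh ROI output and the pre-output decoder features exposed
# for fusion with the global branch.
run_local_generator <- function(gen, roi) {
  cfg <- gen$config
  if (!all(dim(ag_value(roi))[1:2] == cfg$roi_size))
    stop("ROI input must be roi_size x roi_size")
  roi <- as_node(roi)
  skips <- list()
  h <- fw_defc(gen$local$enc0, roi, stride = 1L, pad = 3L)
  skips[[1]] <- h
  for (i in seq_along(gen$local$down)) {
    h <- fw_defres(gen$local$down[[i]], h)
    if (i < length(gen$local$down)) skips[[i + 1L]] <- h
  }
  for (blk in gen$local$fusion) h <- fw_res(blk, h)
  ndl <- cfg$n_downsamples_local
  raw_full <- ag_value(roi)
  for (i in seq_along(gen$local$up)) {
    h <- fw_upconv(gen$local$up[[i]]$convT, h)
    res <- dim(h$value)[1]
    skip <- skips[[ndl - i + 1L]]
    raw <- ag_const(cpp_resize_bilinear(raw_full, res, res))
    h <- fw_spade_res(gen$local$up[[i]]$spade, h, skip, raw)
  }
  out <- ag_tanh(ag_conv2d(h, gen$local$out$W, gen$local$out$b,
                           stride = 1L, pad = 3L))
  list(out = out, fusion_features = h)
}

# ---- fusion ----------------------------------------------------------------

# Element-wise fusion of the local branch's decoder features into the global
# encoder output: 1x1 channel projection, average-pool to the ROI footprint
# at the global bottleneck resolution, embed into zeros at the scaled ROI
# window position, sum.
fuse_features <- function(gen, global_encoded, fusion_features, roi_window) {
  factor <- 2L^gen$config$n_downsamples_global
  gd <- dim(ag_value(global_encoded))
  pf <- ag_conv2d(fusion_features, gen$global$proj$W, gen$global$proj$b,
                  stride = 1L, pad = 0L)
  pooled <- ag_avgpool(pf, factor)
  r0 <- roi_window[["r0"]] %/% factor
  c0 <- roi_window[["c0"]] %/% factor
  pd <- dim(pooled$value)
  if (r0 + pd[1] > gd[1] || c0 + pd[2] > gd[2])
    stop("ROI window outside the global feature map")
  emb <- ag_embed(pooled, gd, r0 + 1L, c0 + 1L)
  ag_add(global_encoded, emb)
}

# ---- content revisor -------------------------------------------------------

# Content revisor: n-1 tanh content masks from the decoder features, one
# channel-attention vector (softmax over the n groups, global pooling + a
# shared fully-connected layer), composed with the input as background.
content_revisor <- function(gen, m, x) {
  n <- gen$config$n_groups
  x <- as_node(x)
  contents <- lapply(gen$revisor$content, function(cl)
    ag_tanh(ag_conv2d(m, cl$W, cl$b, stride = 1L, pad = 1L)))
  amid <- ag_conv2d(m, gen$revisor$attn_conv$W, gen$revisor$attn_conv$b,
                    stride = 1L, pad = 1L)
  fc <- gen$revisor$fc
  att <- ag_softmax(ag_add_vec(ag_dense(ag_gap(amid), fc$W, fc$b),
                               ag_dense(ag_gmp(amid), fc$W, fc$b)))
  out <- ag_attention_compose(c(contents, list(x)), att)
  list(out = out, content_masks = contents, attention = att)
}

# ---- full generator --------------------------------------------------------

#' Run the generator on a B-mode image
#'
#' Extracts the nodule ROI from the mask, runs the local branch, runs the
#' global encoder with spatial attention, fuses the local decoder features
#' into the global bottleneck at the ROI position, decodes with SPADE
#' residual blocks and composes the final image with the content revisor.
#'
#' @param gen A [init_generator()] model.
#' @param bmode H x W grayscale matrix in \[0, 1\], H = W = `global_size`.
#' @param mask H x W binary nodule mask used only for ROI extraction.
#' @return List with `global_out` (H x W x 3 normalized-Lab array in
#'   (-1, 1)), `roi_out` (ROI-sized array), and `diagnostics` (content
#'   masks, attention weights, spatial-attention mask, ROI window).
#' @export
run_generator <- function(gen, bmode, mask) {
  cfg <- gen$config
  if (!all(dim(bmode) == cfg$global_size))
    stop("bmode must be global_size x global_size")
  x_global <- bmode_to_input(bmode)
  roi_info <- extract_roi(bmode, mask, cfg$roi_size)
  fwd <- generator_forward(gen, x_global, roi_info)
  list(global_out = ag_value(fwd$global_out),
       roi_out = ag_value(fwd$roi_out),
       diagnostics = list(
         attention = ag_value(fwd$revisor$attention),
         content_masks = lapply(fwd$revisor$content_masks, ag_value),
         sa_mask = ag_value(fwd$sa_mask),
         roi_window = roi_info$window))
}

# Differentiable forward pass on a prepared normalized-Lab input; used by
# both run_generator (inference) and the training step (with tape).
generator_forward <- function(gen, x_global, roi_info) {
  cfg <- gen$config
  x_roi <- bmode_to_input(roi_info$roi)
  loc <- run_local_generator(gen, ag_const(x_roi))

  xg <- ag_const(x_global)
  h <- ag_conv2d(xg, gen$global$enc0$conv$W, gen$global$enc0$conv$b,
                 stride = 1L, pad = 3L)
  h <- ag_leaky_relu(ag_batchnorm(h, gen$global$enc0$bn$gamma,
                                  gen$global$enc0$bn$beta))
  sa <- fw_sa(gen$global$sa, h)
  h <- sa$out
  skips <- list(h)
  for (i in seq_along(gen$global$down)) {
    blk <- gen$global$down[[i]]
    h <- ag_conv2d(h, blk$conv$W, blk$conv$b, stride = 2L, pad = 1L)
    h <- ag_leaky_relu(ag_batchnorm(h, blk$bn$gamma, blk$bn$beta))
    if (i < length(gen$global$down)) skips[[i + 1L]] <- h
  }
  h <- fuse_features(gen, h, loc$fusion_features, roi_info$window)
  for (blk in gen$global$fusion) h <- fw_res(blk, h)
  ndg <- cfg$n_downsamples_global
  for (i in seq_along(gen$global$up)) {
    h <- fw_upconv(gen$global$up[[i]]$convT, h)
    res <- dim(h$value)[1]
    skip <- skips[[ndg - i + 1L]]
    raw <- ag_const(cpp_resize_bilinear(x_global, res, res))
    h <- fw_spade_res(gen$global$up[[i]]$spade, h, skip, raw)
  }
  rev <- content_revisor(gen, h, ag_const(x_global))
  list(global_out = rev$out, roi_out = loc$out, revisor = rev,
       sa_mask = sa$mask, roi_window = roi_info$window)
}
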