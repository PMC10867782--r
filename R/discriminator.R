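# Conditional PatchGAN discriminators. The two discriminators (global and
# ROI scale) share this architecture and differ only in their parameters.

#' Discriminator configuration
#'
#' @param n_layers Number of strided 4x4 convolution stages T (the stages
#'   whose features feed the feature-matching loss); must be >= 2.
#' @param base_channels Channel width of the first stage.
#' @param in_channels Channels of the concatenated (source, target) input.
#' @param seed Seed for weight initialization.
#' @return Object of class `discriminator_config`.
#' @export
discriminator_config <- function(n_layers = 4L, base_channels = 64L,
                                 in_channels = 6L, seed = 1L) {
  if (n_layers < 2L) stop("n_layers must be at least 2 for feature matching")
  structure(list(n_layers = as.integer(n_layers),
                 base_channels = as.integer(base_channels),
                 in_channels = as.integer(in_channels),
                 seed = as.integer(seed)),
            class = "discriminator_config")
}

#' Initialize a PatchGAN discriminator
#' @param config A [discriminator_config()].
#' @return Object of class `tsegan_discriminator`.
#' @export
init_discriminator <- function(config = discriminator_config()) {
  stopifnot(inherits(config, "discriminator_config"))
  b <- config$base_channels
  with_seed(config$seed, {
    stages <- lapply(seq_len(config$n_layers), function(i) {
      cin <- if (i == 1L) config$in_channels else b * 2L^(i - 2L)
      cout <- b * 2L^(i - 1L)
      list(conv = conv_layer(4L, 4L, cin, cout),
           bn = if (i > 1L) bn_layer(cout) else NULL)
    })
    out <- conv_layer(4L, 4L, b * 2L^(config$n_layers - 1L), 1L)
    structure(list(stages = stages, out = out, config = config),
              class = "tsegan_discriminator")
  })
}

#' Conditional patch discrimination
#'
#' Channel-concatenates the source and target images and applies T strided
#' 4x4 convolution stages (each halving resolution and doubling channels)
#' followed by a 1-channel output convolution. Returns raw logits (no
#' sigmoid; the stable adversarial loss consumes logits directly) and the T
#' intermediate feature maps for the feature-matching loss.
#'
#' @param disc A [init_discriminator()] model.
#' @param source,target Images (arrays or autodiff nodes) of identical
#'   resolution, both in normalized Lab.
#' @return List with `logits` (node, h x w x 1) and `features`
#'   (list of T nodes).
#' @export
patch_discriminate <- function(disc, source, target) {
  sd_ <- dim(ag_value(source)); td <- dim(ag_value(target))
  if (!all(sd_[1:2] == td[1:2]))
    stop("source and target resolutions differ")
  h <- ag_concat_c(list(as_node(source), as_node(target)))
  if (dim(h$value)[3] != disc$config$in_channels)
    stop("channel count does not match discriminator input")
  features <- vector("list", disc$config$n_layers)
  for (i in seq_along(disc$stages)) {
    st <- disc$stages[[i]]
    h <- ag_conv2d(h, st$conv$W, st$conv$b, stride = 2L, pad = 1L)
    if (!is.null(st$bn)) h <- ag_batchnorm(h, st$bn$gamma, st$bn$beta)
    h <- ag_leaky_relu(h)
    features[[i]] <- h
  }
  logits <- ag_conv2d(h, disc$out$W, disc$out$b, stride = 1L, pad = 1L)
  list(logits = logits, features = features)
}
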