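# sRGB <-> CIELAB conversion (D65 white point, 2 degree observer), the
# symmetric normalization used for network tensors, Gaussian blur, and
# channel-distribution diagnostics.
#
# Lab images are H x W x 3 arrays with channels (L, a, b): L in [0, 100],
# a and b nominally in [-128, 127].

.srgb_to_xyz <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                         0.2126729, 0.7151522, 0.0721750,
                         0.0193339, 0.1191920, 0.9503041),
                       nrow = 3, byrow = TRUE)
.xyz_to_srgb <- solve(.srgb_to_xyz)
.d65 <- c(0.95047, 1.0, 1.08883)

#' Convert an sRGB image to CIELAB
#'
#' Standard sRGB (D65) conversion: gamma expansion, linear map to XYZ, then
#' the CIELAB cube-root encoding. The loss functions of the network operate
#' on this representation because elastogram colors occupy a much more
#' concentrated region of Lab space than of RGB space.
#'
#' @param rgb H x W x 3 array with values in \[0, 1\].
#' @return H x W x 3 array with channels (L, a, b).
#' @export
#' @examples
#' rgb_to_lab(array(1, dim = c(1, 1, 3)))  # white -> (100, 0, 0)
rgb_to_lab <- function(rgb) {
  d <- dim(rgb)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop("rgb must be an H x W x 3 array")
  if (min(rgb) < -1e-9 || max(rgb) > 1 + 1e-9)
    stop("rgb values must lie in [0, 1]")
  m <- matrix(pmin(pmax(rgb, 0), 1), ncol = 3L)
  lin <- ifelse(m <= 0.04045, m / 12.92, ((m + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.srgb_to_xyz)
  t0 <- (6 / 29)^3
  fr <- sweep(xyz, 2, .d65, "/")
  f <- ifelse(fr > t0, fr^(1 / 3), fr / (3 * (6 / 29)^2) + 4 / 29)
  L <- 116 * f[, 2] - 16
  a <- 500 * (f[, 1] - f[, 2])
  b <- 200 * (f[, 2] - f[, 3])
  array(c(L, a, b), dim = d)
}

#' Convert a CIELAB image to sRGB
#'
#' Inverse of [rgb_to_lab()]. Out-of-gamut results are clipped to \[0, 1\];
#' the number of clipped components is reported as a message when nonzero.
#'
#' @param lab H x W x 3 array with channels (L, a, b).
#' @param quiet Suppress the clipping message.
#' @return H x W x 3 sRGB array in \[0, 1\].
#' @export
lab_to_rgb <- function(lab, quiet = FALSE) {
  d <- dim(lab)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop("lab must be an H x W x 3 array")
  m <- matrix(lab, ncol = 3L)
  fy <- (m[, 1] + 16) / 116
  fx <- fy + m[, 2] / 500
  fz <- fy - m[, 3] / 200
  finv <- function(f) ifelse(f > 6 / 29, f^3, 3 * (6 / 29)^2 * (f - 4 / 29))
  xyz <- cbind(finv(fx) * .d65[1], finv(fy) * .d65[2], finv(fz) * .d65[3])
  lin <- xyz %*% t(.xyz_to_srgb)
  srgb <- ifelse(lin <= 0.0031308, 12.92 * lin,
                 1.055 * pmax(lin, 0)^(1 / 2.4) - 0.055)
  nclip <- sum(srgb < 0 | srgb > 1)
  if (nclip > 0 && !quiet)
    message(sprintf("lab_to_rgb: clipped %d out-of-gamut components", nclip))
  array(pmin(pmax(srgb, 0), 1), dim = d)
}

#' Map a Lab image onto the symmetric \[-1, 1\] network range
#'
#' Affine per channel: L maps \[0, 100\] -> \[-1, 1\]; a and b map
#' \[-128, 127\] -> \[-1, 1\]. [denormalize_lab()] is the exact inverse.
#'
#' @param lab H x W x 3 Lab array.
#' @return H x W x 3 array in \[-1, 1\].
#' @export
normalize_lab <- function(lab) {
  out <- lab
  out[, , 1] <- lab[, , 1] / 50 - 1
  out[, , 2] <- (lab[, , 2] + 128) / 127.5 - 1
  out[, , 3] <- (lab[, , 3] + 128) / 127.5 - 1
  out
}

#' @rdname normalize_lab
#' @param x H x W x 3 normalized array.
#' @export
denormalize_lab <- function(x) {
  out <- x
  out[, , 1] <- (x[, , 1] + 1) * 50
  out[, , 2] <- (x[, , 2] + 1) * 127.5 - 128
  out[, , 3] <- (x[, , 3] + 1) * 127.5 - 128
  out
}

#' Normalized 2-D Gaussian kernel
#'
#' @param size Odd kernel width (pixels).
#' @param sigma Standard deviation (pixels).
#' @return Object of class `gaussian_kernel`: list with `size`, `sigma` and
#'   the `size` x `size` matrix `weights` summing to 1.
#' @export
gaussian_kernel <- function(size = 21L, sigma = 3) {
  size <- as.integer(size)
  if (size %% 2L == 0L) stop("kernel size must be odd")
  if (sigma <= 0) stop("sigma must be positive")
  r <- (size - 1L) %/% 2L
  g1 <- exp(-((-r):r)^2 / (2 * sigma^2))
  g1 <- g1 / sum(g1)
  structure(list(size = size, sigma = sigma, weights = outer(g1, g1),
                 g1 = g1),
            class = "gaussian_kernel")
}

#' Gaussian blur with reflect padding
#'
#' Per-channel 2-D convolution of the image with a normalized Gaussian
#' kernel; symmetric (mirror) padding keeps the image mean unchanged. Linear
#' in the input.
#'
#' @param image H x W x C array (a grayscale H x W matrix is accepted).
#' @param kernel A [gaussian_kernel()] object.
#' @return Blurred array of the same shape.
#' @export
gaussian_blur <- function(image, kernel = gaussian_kernel()) {
  if (!inherits(kernel, "gaussian_kernel")) stop("kernel must be a gaussian_kernel")
  two_d <- is.matrix(image)
  if (two_d) image <- array(image, dim = c(dim(image), 1L))
  node <- ag_no_grad(ag_blur(ag_const(image), kernel$weights, kernel$g1))
  out <- node$value
  if (two_d) out <- out[, , 1]
  out
}

#' Per-channel Shannon entropy of pooled pixel values
#'
#' Pools the pixels of a set of images, histograms each channel into
#' `bins` equal-width bins over the channel's nominal range, and returns the
#' Shannon entropy in bits. Used to compare how concentrated elastogram
#' colors are in RGB versus Lab coordinates.
#'
#' @param images List of H x W x 3 arrays (sRGB in \[0,1\] or Lab).
#' @param space `"rgb"` or `"lab"` — fixes the histogram ranges.
#' @param bins Number of histogram bins per channel.
#' @return Named numeric vector of three entropies (bits).
#' @export
channel_entropy <- function(images, space = c("rgb", "lab"), bins = 64L) {
  space <- match.arg(space)
  if (length(images) == 0L) stop("need at least one image")
  ranges <- if (space == "rgb") {
    list(c(0, 1), c(0, 1), c(0, 1))
  } else {
    list(c(0, 100), c(-128, 127), c(-128, 127))
  }
  pooled <- lapply(1:3, function(ch) {
    unlist(lapply(images, function(im) as.vector(im[, , ch])), use.names = FALSE)
  })
  ent <- vapply(1:3, function(ch) {
    rg <- ranges[[ch]]
    v <- pmin(pmax(pooled[[ch]], rg[1]), rg[2])
    cuts <- seq(rg[1], rg[2], length.out = bins + 1L)
    counts <- tabulate(pmin(findInterval(v, cuts, rightmost.closed = TRUE), bins),
                       nbins = bins)
    p <- counts / sum(counts)
    p <- p[p > 0]
    -sum(p * log2(p))
  }, 0)
  names(ent) <- if (space == "rgb") c("R", "G", "B") else c("L", "a", "b")
  ent
}
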