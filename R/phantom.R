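# Seeded synthetic paired B-mode / strain-elastogram phantoms.
#
# Clinical strain elastography renders stiffness as color: green for elastic
# tissue, blue for stiff (sclerotic) tissue, with a 1-5 Rago score read off
# the blue/green composition inside the nodule. The phantoms emulate that
# reading: a speckled grayscale background with a hypoechoic elliptical
# nodule (B-mode proxy), and a co-registered elastogram whose nodule
# contains a central blue core occupying a designed area fraction per score.
# Stiffer (higher-score) nodules are drawn darker, so the stiffness signal
# is recoverable from the B-mode alone.

# Designed blue-area fraction bands per Rago score. The generator samples a
# target fraction from the inner sub-band so that discretization and the
# angular wobble of the core boundary cannot push the realized fraction
# outside the design band.
.rago_bands <- list(`1` = c(0.00, 0.05), `2` = c(0.15, 0.35),
                    `3` = c(0.40, 0.60), `4` = c(0.65, 0.85),
                    `5` = c(0.95, 1.00))
.rago_targets <- list(`1` = c(0.015, 0.035), `2` = c(0.20, 0.30),
                      `3` = c(0.45, 0.55), `4` = c(0.70, 0.80),
                      `5` = c(0.955, 0.985))

#' Design bands of the phantom blue-area fraction per Rago score
#' @return Named list of length-2 numeric ranges.
#' @export
rago_bands <- function() .rago_bands

with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

#' Phantom generator configuration
#'
#' @param image_size Image side length in pixels (square images).
#' @param nodule_radius_range Min and max ellipse semi-axis (pixels).
#' @param target_score Integer Rago score 1-5, or `"random"` for balanced
#'   assignment in [generate_dataset()].
#' @param speckle_scale Intensity of the multiplicative Rayleigh-like
#'   speckle (0 = none).
#' @param spot_density Expected fraction of background pixels covered by
#'   sparse red/yellow artifact spots.
#' @param seed Integer seed; phantoms are a pure function of the config.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 256L,
                           nodule_radius_range = c(20, 60),
                           target_score = "random",
                           speckle_scale = 0.35,
                           spot_density = 0.01,
                           seed = 1L) {
  image_size <- as.integer(image_size)
  if (image_size < 64L) stop("image_size must be at least 64")
  if (length(nodule_radius_range) != 2L || any(nodule_radius_range <= 0) ||
      nodule_radius_range[1] > nodule_radius_range[2])
    stop("nodule_radius_range must be an increasing positive pair")
  if (image_size < 2 * max(nodule_radius_range))
    stop("image_size must be at least twice the maximum nodule radius")
  if (!identical(target_score, "random")) {
    if (!(is.numeric(target_score) && length(target_score) == 1L &&
          target_score %in% 1:5))
      stop("target_score must be 1..5 or \"random\"")
    target_score <- as.integer(target_score)
  }
  if (spot_density < 0 || spot_density > 1) stop("spot_density must be in [0, 1]")
  if (speckle_scale < 0) stop("speckle_scale must be nonnegative")
  structure(list(image_size = image_size,
                 nodule_radius_range = as.numeric(nodule_radius_range),
                 target_score = target_score,
                 speckle_scale = speckle_scale,
                 spot_density = spot_density,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Smoothed standard-normal field, rescaled to unit variance.
smooth_noise_field <- function(n, sigma) {
  z <- matrix(rnorm(n * n), n, n)
  k <- gaussian_kernel(min(2L * ceiling(2 * sigma) + 1L, 2L * (n %/% 2L) - 1L), sigma)
  s <- gaussian_blur(z, k)
  s / max(sd(s), 1e-12)
}

#' Generate one paired B-mode / elastogram phantom
#'
#' Deterministic given the config (including its seed). The B-mode is a
#' smoothed background texture under multiplicative speckle with a darker
#' elliptical nodule whose luminance drop grows with the stiffness score.
#' The elastogram is green-dominant, carries a central blue core inside the
#' nodule occupying the score's designed area fraction, sparse red/yellow
#' spots outside the nodule, and is luminance-modulated by the (smoothed)
#' B-mode so the two modalities co-register.
#'
#' @param config A [phantom_config()].
#' @return Object of class `paired_sample`: list with `bmode` (H x W matrix
#'   in \[0,1\]), `elastogram` (H x W x 3 sRGB array), `mask` (H x W 0/1
#'   integer matrix), `score` (integer 1-5), `id` (string), and the realized
#'   `blue_fraction`.
#' @export
generate_phantom_pair <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$image_size
  with_seed(config$seed, {
    score <- if (identical(config$target_score, "random"))
      sample(1:5, 1L) else config$target_score

    rmax <- config$nodule_radius_range[2]
    ci <- runif(1, rmax + 2, n - rmax - 1)
    cj <- runif(1, rmax + 2, n - rmax - 1)
    ra <- runif(1, config$nodule_radius_range[1], rmax)
    rb <- runif(1, config$nodule_radius_range[1], rmax)
    phi <- runif(1, 0, pi)

    ii <- matrix(seq_len(n), n, n) - ci
    jj <- matrix(seq_len(n), n, n, byrow = TRUE) - cj
    u <- ii * cos(phi) + jj * sin(phi)
    v <- -ii * sin(phi) + jj * cos(phi)
    rho <- sqrt((u / ra)^2 + (v / rb)^2)  # elliptical radius, boundary at 1
    mask <- (rho <= 1) * 1L

    # B-mode: base texture, score-dependent hypoechoic nodule, speckle
    base <- 0.55 + 0.10 * smooth_noise_field(n, max(2, n / 32))
    drop <- (0.12 + 0.045 * score) * stats::plogis((1 - rho) / 0.05)
    lum <- base - drop
    if (config$speckle_scale > 0) {
      ray <- sqrt(matrix(rnorm(n * n)^2 + rnorm(n * n)^2, n, n))
      spk <- ray / sqrt(pi / 2)
      spk <- gaussian_blur(spk, gaussian_kernel(13L, 2))
      spk <- spk / mean(spk)
      lum <- lum * (1 + config$speckle_scale * (spk - 1))
    }
    bmode <- pmin(pmax(lum, 0), 1)

    # Elastogram: green background, central blue core of designed area
    # fraction (core boundary gets a small angular wobble), sparse spots.
    tgt <- .rago_targets[[as.character(score)]]
    f <- runif(1, tgt[1], tgt[2])
    theta <- atan2(v, u)
    a1 <- runif(1, -0.03, 0.03); a2 <- runif(1, -0.03, 0.03)
    p1 <- runif(1, 0, 2 * pi); p2 <- runif(1, 0, 2 * pi)
    # rank nodule pixels by angularly-wobbled elliptical radius and take
    # exactly the floor(f * area) innermost — the realized fraction then
    # sits in the design band regardless of nodule size
    wobble <- 1 + a1 * sin(2 * theta + p1) + a2 * sin(3 * theta + p2)
    rho_w <- rho / pmax(wobble, 0.5)
    nod_idx <- which(mask == 1L)
    n_blue <- floor(f * length(nod_idx))
    blue_core <- matrix(FALSE, n, n)
    if (n_blue > 0) {
      ord <- nod_idx[order(rho_w[nod_idx])]
      blue_core[ord[seq_len(n_blue)]] <- TRUE
    }

    green <- c(0.10, 0.80, 0.16)
    blue <- c(0.08, 0.18, 0.88)
    ela <- array(rep(green, each = n * n), dim = c(n, n, 3))
    for (ch in 1:3) {
      pl <- ela[, , ch]
      pl[blue_core] <- blue[ch]
      ela[, , ch] <- pl
    }

    # sparse red/yellow spots strictly outside the nodule
    bg_idx <- which(rho > 1.3)
    spot_area <- pi * 3^2
    n_spots <- round(config$spot_density * length(bg_idx) / spot_area)
    if (n_spots > 0 && length(bg_idx) > 0) {
      centers <- sample(bg_idx, min(n_spots, length(bg_idx)))
      for (ctr in centers) {
        si <- (ctr - 1L) %% n + 1L
        sj <- (ctr - 1L) %/% n + 1L
        sr <- runif(1, 2, 4)
        col <- if (runif(1) < 0.5) c(0.85, 0.18, 0.10) else c(0.88, 0.82, 0.12)
        di <- matrix(seq_len(n), n, n) - si
        dj <- matrix(seq_len(n), n, n, byrow = TRUE) - sj
        inside <- di^2 + dj^2 <= sr^2 & rho > 1.05
        for (ch in 1:3) {
          pl <- ela[, , ch]
          pl[inside] <- col[ch]
          ela[, , ch] <- pl
        }
      }
    }

    noise <- array(runif(n * n * 3, -0.05, 0.05), dim = c(n, n, 3))
    ela <- ela + noise
    lum_mod <- 0.6 + 0.4 * gaussian_blur(bmode, gaussian_kernel(13L, 2))
    for (ch in 1:3) ela[, , ch] <- ela[, , ch] * lum_mod
    ela <- pmin(pmax(ela, 0), 1)

    structure(list(bmode = bmode, elastogram = ela, mask = mask,
                   score = score, id = sprintf("phantom_s%d_seed%d", score,
                                               config$seed),
                   blue_fraction = mean(blue_core[mask == 1L])),
              class = "paired_sample")
  })
}

#' Fraction of blue-dominant pixels inside a mask
#'
#' The programmatic stiffness reading: the fraction of mask pixels whose
#' blue channel strictly exceeds both the red and the green channel.
#'
#' @param elastogram H x W x 3 color array.
#' @param mask H x W binary matrix (nonzero = inside).
#' @return Fraction in \[0, 1\].
#' @export
blue_green_ratio <- function(elastogram, mask) {
  d <- dim(elastogram)
  if (length(d) != 3L || d[3] != 3L) stop("elastogram must be H x W x 3")
  if (!all(d[1:2] == dim(mask))) stop("elastogram and mask shapes differ")
  sel <- mask != 0
  if (!any(sel)) stop("mask is empty")
  r <- elastogram[, , 1][sel]
  g <- elastogram[, , 2][sel]
  b <- elastogram[, , 3][sel]
  mean(b > r & b > g)
}

#' Map a blue/green ratio to a proxy Rago score
#'
#' Fixed thresholds aligned with the phantom design bands. A programmatic
#' stand-in for human elasticity scoring, for phantom evaluation only.
#'
#' @param ratio Blue-dominant fraction in \[0, 1\].
#' @return Integer score 1-5.
#' @export
proxy_rago_score <- function(ratio) {
  as.integer(cut(ratio, c(-Inf, 0.05, 0.35, 0.60, 0.85, Inf), labels = FALSE))
}

#' Extract a square region of interest centered on a mask
#'
#' Returns the `roi_size` crop centered on the mask centroid, with the
#' window clamped to the image bounds so the crop always has full size and
#' contains only real pixels. The window is reported in 0-based half-open
#' coordinates for later feature placement.
#'
#' @param image H x W matrix or H x W x C array.
#' @param mask H x W binary matrix. If empty, the image center is used with
#'   a warning.
#' @param roi_size Crop side length (pixels).
#' @return List with `roi` (the crop) and `window` =
#'   `c(r0, r1, c0, c1)` (0-based, half-open).
#' @export
extract_roi <- function(image, mask, roi_size = 128L) {
  roi_size <- as.integer(roi_size)
  d <- dim(image)
  H <- d[1]; W <- d[2]
  if (H < roi_size || W < roi_size) stop("image smaller than roi_size")
  if (any(mask != 0)) {
    idx <- which(mask != 0, arr.ind = TRUE)
    centroid <- colMeans(idx) - 1  # 0-based
  } else {
    warning("empty mask; falling back to the image center")
    centroid <- c((H - 1) / 2, (W - 1) / 2)
  }
  r0 <- min(max(round(centroid[1] - roi_size / 2), 0), H - roi_size)
  c0 <- min(max(round(centroid[2] - roi_size / 2), 0), W - roi_size)
  roi <- if (length(d) == 2L) {
    image[(r0 + 1):(r0 + roi_size), (c0 + 1):(c0 + roi_size)]
  } else {
    image[(r0 + 1):(r0 + roi_size), (c0 + 1):(c0 + roi_size), , drop = FALSE]
  }
  list(roi = roi,
       window = c(r0 = unname(r0), r1 = unname(r0) + roi_size,
                  c0 = unname(c0), c1 = unname(c0) + roi_size))
}

#' Coarse threshold segmentation of a hypoechoic nodule
#'
#' Smooths the B-mode, thresholds at the midpoint between the 2nd and 60th
#' intensity percentiles (the nodule interior versus the background bulk —
#' robust when the dark class is a small image fraction, where a global
#' Otsu split degenerates), severs thin speckle bridges with a morphological
#' opening, keeps the dark component containing the darkest pixel, and
#' fills holes. A deliberately coarse fallback for mask-free inference on
#' arbitrary images; training always uses ground-truth masks.
#'
#' @param bmode H x W grayscale matrix in \[0, 1\].
#' @return H x W 0/1 integer matrix.
#' @export
naive_segment <- function(bmode) {
  if (sd(bmode) < 1e-12) stop("cannot segment a constant image")
  g <- gaussian_blur(bmode, gaussian_kernel(17L, 4))
  thr <- 0.5 * (quantile(g, 0.02) + quantile(g, 0.60))
  dark <- EBImage::Image((g < thr) * 1)
  opened <- EBImage::opening(dark, EBImage::makeBrush(3L, "disc"))
  labm <- EBImage::imageData(EBImage::bwlabel(opened))
  if (max(labm) < 1) return(matrix(0L, nrow(bmode), ncol(bmode)))
  keep_lab <- labm[which.min(g)]
  if (keep_lab == 0) {  # darkest pixel eroded away: fall back to darkness mass
    mass <- vapply(seq_len(max(labm)), function(l) sum((thr - g)[labm == l]), 0)
    keep_lab <- which.max(mass)
  }
  filled <- EBImage::fillHull(EBImage::Image((labm == keep_lab) * 1))
  matrix(as.integer(EBImage::imageData(filled) > 0), nrow(bmode), ncol(bmode))
}

#' Write a dataset of phantom pairs to disk
#'
#' Generates `n` phantoms (scores balanced over 1-5 when the config's
#' `target_score` is `"random"`), writes each as an 8-bit PNG triplet
#' (B-mode, elastogram, mask) and records them in a tab-separated manifest
#' with columns `id`, `bmode_path`, `se_path`, `mask_path`, `score`
#' (paths relative to the manifest's directory).
#'
#' @param n Number of pairs (>= 1).
#' @param config A [phantom_config()]; per-sample seeds are derived from its
#'   seed.
#' @param out_dir Output directory (created if needed).
#' @return Path to the manifest file, invisibly.
#' @export
generate_dataset <- function(n, config = phantom_config(), out_dir) {
  stopifnot(n >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  scores <- if (identical(config$target_score, "random")) {
    with_seed(config$seed, sample(rep_len(1:5, n)))
  } else {
    rep(config$target_score, n)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    seed_i <- (config$seed + i * 1000003L) %% .Machine$integer.max
    cfg <- config
    cfg$target_score <- scores[i]
    cfg$seed <- as.integer(seed_i)
    smp <- generate_phantom_pair(cfg)
    id <- sprintf("ph%04d", i)
    bp <- paste0(id, "_bmode.png")
    sp <- paste0(id, "_se.png")
    mp <- paste0(id, "_mask.png")
    png::writePNG(smp$bmode, file.path(out_dir, bp))
    png::writePNG(smp$elastogram, file.path(out_dir, sp))
    png::writePNG(smp$mask + 0, file.path(out_dir, mp))
    rows[[i]] <- data.frame(id = id, bmode_path = bp, se_path = sp,
                            mask_path = mp, score = smp$score,
                            stringsAsFactors = FALSE)
  }
  manifest <- file.path(out_dir, "manifest.tsv")
  write.table(do.call(rbind, rows), manifest, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(manifest)
}

#' Read a phantom dataset manifest
#' @param manifest Path to a manifest written by [generate_dataset()].
#' @return Data frame with absolute paths.
#' @export
read_manifest <- function(manifest) {
  df <- read.delim(manifest, stringsAsFactors = FALSE)
  need <- c("id", "bmode_path", "se_path", "mask_path", "score")
  if (!all(need %in% names(df))) stop("manifest lacks required columns")
  base <- dirname(normalizePath(manifest))
  for (cn in c("bmode_path", "se_path", "mask_path"))
    df[[cn]] <- ifelse(grepl("^/", df[[cn]]), df[[cn]], file.path(base, df[[cn]]))
  df
}

#' Load one paired sample from manifest paths
#' @param row One row of a [read_manifest()] data frame.
#' @return A `paired_sample` list.
#' @export
load_sample <- function(row) {
  bm <- png::readPNG(row$bmode_path)
  if (length(dim(bm)) == 3L) bm <- bm[, , 1]
  se <- png::readPNG(row$se_path)
  if (length(dim(se)) == 3L && dim(se)[3] > 3L) se <- se[, , 1:3]
  mk <- png::readPNG(row$mask_path)
  if (length(dim(mk)) == 3L) mk <- mk[, , 1]
  structure(list(bmode = bm, elastogram = se,
                 mask = matrix(as.integer(mk > 0.5), nrow(mk), ncol(mk)),
                 score = as.integer(row$score), id = row$id),
            class = "paired_sample")
}
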