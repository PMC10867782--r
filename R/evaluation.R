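# Image-quality metrics (PSNR, SSIM, MSE on 8-bit renderings) and model
# evaluation reports, including the blue/green-ratio stiffness proxy.

#' Peak signal-to-noise ratio
#'
#' `10 log10(MAX^2 / mean((I-G)^2))` with the mean over all H*W*C elements
#' and MAX = 255 (8-bit). Identical images would give +Inf; those are
#' reported at a 100 dB sentinel cap.
#'
#' @param I,G Images on the 0..255 scale, identical shape.
#' @param max_val Maximum intensity (255 for 8-bit).
#' @param cap Sentinel for the zero-error limit (dB).
#' @return PSNR in dB.
#' @export
psnr <- function(I, G, max_val = 255, cap = 100) {
  if (!identical(dim(I), dim(G))) stop("shape mismatch")
  err <- mean((as.numeric(I) - as.numeric(G))^2)
  if (err == 0) return(cap)
  min(10 * log10(max_val^2 / err), cap)
}

#' Mean squared error
#'
#' Mean squared difference over the H*W pixel grid; multichannel images are
#' additionally averaged over channels, so the PSNR identity
#' `psnr = 10 log10(255^2 / mse)` holds exactly.
#'
#' @param I,G Images of identical shape.
#' @return Mean squared error.
#' @export
mse <- function(I, G) {
  if (!identical(dim(I), dim(G))) stop("shape mismatch")
  mean((as.numeric(I) - as.numeric(G))^2)
}

#' Structural similarity index
#'
#' `"global"` evaluates the SSIM formula once from whole-image moments;
#' `"windowed"` (the community convention, the default) averages the
#' formula over 11x11 Gaussian windows (sigma 1.5) at every pixel, per
#' channel. Stabilizers c1 = (0.01 MAX)^2, c2 = (0.03 MAX)^2.
#'
#' @param I,G Images on the 0..255 scale, identical shape.
#' @param mode `"windowed"` or `"global"`.
#' @param max_val Dynamic range (255 for 8-bit).
#' @return SSIM in \[-1, 1\].
#' @export
ssim <- function(I, G, mode = c("windowed", "global"), max_val = 255) {
  mode <- match.arg(mode)
  if (!identical(dim(I), dim(G))) stop("shape mismatch")
  c1 <- (0.01 * max_val)^2
  c2 <- (0.03 * max_val)^2
  I <- as.array(I) * 1.0; G <- as.array(G) * 1.0
  if (mode == "global") {
    mi <- mean(I); mg <- mean(G)
    vi <- mean((I - mi)^2); vg <- mean((G - mg)^2)
    cv <- mean((I - mi) * (G - mg))
    return(((2 * mi * mg + c1) * (2 * cv + c2)) /
             ((mi^2 + mg^2 + c1) * (vi + vg + c2)))
  }
  d <- dim(I)
  if (length(d) == 2L) { I <- array(I, c(d, 1L)); G <- array(G, c(d, 1L)); d <- dim(I) }
  if (d[1] < 11L || d[2] < 11L) stop("image smaller than the 11x11 SSIM window")
  k <- gaussian_kernel(11L, 1.5)
  mu_i <- gaussian_blur(I, k); mu_g <- gaussian_blur(G, k)
  s_ii <- gaussian_blur(I * I, k) - mu_i^2
  s_gg <- gaussian_blur(G * G, k) - mu_g^2
  s_ig <- gaussian_blur(I * G, k) - mu_i * mu_g
  map <- ((2 * mu_i * mu_g + c1) * (2 * s_ig + c2)) /
    ((mu_i^2 + mu_g^2 + c1) * (s_ii + s_gg + c2))
  mean(map)
}

to_uint8 <- function(x) round(pmin(pmax(x, 0), 1) * 255)

#' Evaluate a trained generator on a held-out manifest
#'
#' Runs the generator on each B-mode image, renders the normalized-Lab
#' output to 8-bit sRGB, and computes PSNR, SSIM and MSE against the
#' ground-truth elastogram plus the blue/green ratio and proxy Rago score
#' inside the true nodule mask.
#'
#' @param checkpoint Checkpoint path, or a `tsegan_generator`.
#' @param manifest Manifest path of the held-out set.
#' @param out_csv Optional path for the per-image CSV report (aggregate row
#'   appended with id `"mean"`).
#' @param ssim_mode Passed to [ssim()].
#' @return Object of class `eval_report`: list with `per_image` (data
#'   frame) and `aggregate` (named means).
#' @export
evaluate_model <- function(checkpoint, manifest, out_csv = NULL,
                           ssim_mode = "windowed") {
  gen <- if (inherits(checkpoint, "tsegan_generator")) checkpoint
         else load_generator(checkpoint)
  df <- read_manifest(manifest)
  size <- gen$config$global_size
  rows <- list()
  for (i in seq_len(nrow(df))) {
    s <- tryCatch(load_sample(df[i, ]), error = function(e) {
      warning("skipping unreadable manifest row ", i); NULL
    })
    if (is.null(s)) next
    if (!all(dim(s$bmode) == size)) {
      s$bmode <- resize_image(s$bmode, size, size)
      s$elastogram <- resize_image(s$elastogram, size, size)
      s$mask <- matrix(as.integer(resize_nearest(s$mask, size, size) > 0.5),
                       size, size)
    }
    out <- run_generator(gen, s$bmode, s$mask)
    gen_rgb <- output_to_rgb(out$global_out)
    g8 <- to_uint8(gen_rgb)
    t8 <- to_uint8(s$elastogram)
    bg <- if (any(s$mask != 0)) blue_green_ratio(gen_rgb, s$mask) else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      id = s$id, score = s$score,
      psnr = psnr(t8, g8), ssim = ssim(t8, g8, ssim_mode), mse = mse(t8, g8),
      blue_green_ratio = bg,
      proxy_score = if (is.na(bg)) NA_integer_ else proxy_rago_score(bg),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no usable samples in manifest")
  per_image <- do.call(rbind, rows)
  aggregate <- c(psnr = mean(per_image$psnr), ssim = mean(per_image$ssim),
                 mse = mean(per_image$mse),
                 blue_green_ratio = mean(per_image$blue_green_ratio, na.rm = TRUE))
  if (!is.null(out_csv)) {
    agg_row <- data.frame(id = "mean", score = NA,
                          psnr = aggregate[["psnr"]], ssim = aggregate[["ssim"]],
                          mse = aggregate[["mse"]],
                          blue_green_ratio = aggregate[["blue_green_ratio"]],
                          proxy_score = NA, stringsAsFactors = FALSE)
    write.csv(rbind(per_image, agg_row), out_csv, row.names = FALSE)
  }
  structure(list(per_image = per_image, aggregate = aggregate),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d images:\n", nrow(x$per_image)))
  cat(sprintf("  mean PSNR %.3f dB | mean SSIM %.4f | mean MSE %.3f\n",
              x$aggregate[["psnr"]], x$aggregate[["ssim"]],
              x$aggregate[["mse"]]))
  if (!all(is.na(x$per_image$blue_green_ratio)))
    cat(sprintf("  mean blue/green ratio in nodule %.3f\n",
                x$aggregate[["blue_green_ratio"]]))
  invisible(x)
}
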