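# Training recipe: paired augmentation, two-time-scale Adam updates
# (discriminators then generator, one step each per iteration), seeded
# reproducibility and periodic checkpoints.

#' Training configuration
#'
#' Defaults follow the full-scale recipe (1,500 epochs, batch 8, learning
#' rates 2e-4 / 1e-4, Adam betas 0.5 / 0.999, augmentation probability 0.5,
#' translations within 20 px, rotations within 15 degrees, 256 px crops).
#' See [desk_train_config()] for the CPU-scale profile.
#'
#' @param epochs Maximum epochs.
#' @param batch_size Samples per iteration.
#' @param lr_g,lr_d Generator / discriminator learning rates.
#' @param adam_beta1,adam_beta2 Adam moment decays.
#' @param augment_prob Per-transform application probability.
#' @param max_translate Translation bound (pixels, per transform).
#' @param max_rotate Rotation bound (degrees).
#' @param crop_size Training crop (must equal the network's global size).
#' @param resize_margin Pixels added before the random crop.
#' @param seed Master seed; every random draw derives from it.
#' @param checkpoint_every Iterations between checkpoints.
#' @param max_iters Optional hard cap on total iterations.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 1500L, batch_size = 8L, lr_g = 2e-4,
                         lr_d = 1e-4, adam_beta1 = 0.5, adam_beta2 = 0.999,
                         augment_prob = 0.5, max_translate = 20,
                         max_rotate = 15, crop_size = 256L,
                         resize_margin = 32L, seed = 42L,
                         checkpoint_every = 100L, max_iters = NULL) {
  if (lr_g <= 0 || lr_d <= 0) stop("learning rates must be positive")
  if (augment_prob < 0 || augment_prob > 1) stop("augment_prob must be in [0, 1]")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr_g = lr_g, lr_d = lr_d, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, augment_prob = augment_prob,
                 max_translate = max_translate, max_rotate = max_rotate,
                 crop_size = as.integer(crop_size),
                 resize_margin = as.integer(resize_margin),
                 seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every),
                 max_iters = if (is.null(max_iters)) NULL else as.integer(max_iters)),
            class = "train_config")
}

#' Desk-scale training profile
#'
#' CPU-sized study conditions: 64 px crops, batch 4 (half the full-scale
#' batch, keeping gradient averaging close to the reference schedule while
#' bounding the step cost on one CPU), 200 iterations, translations within
#' 5 px (scaled to the smaller frame). Learning rates, Adam settings and
#' loss weights are unchanged from the full recipe.
#' @param seed Master seed.
#' @param max_iters Total iterations.
#' @return A [train_config()].
#' @export
desk_train_config <- function(seed = 42L, max_iters = 200L) {
  train_config(epochs = 10000L, batch_size = 4L, crop_size = 64L,
               max_translate = 5, resize_margin = 8L, seed = seed,
               checkpoint_every = 100L, max_iters = max_iters)
}

# ---- geometric transforms --------------------------------------------------

# Inverse-mapped affine warp: rotate by theta (degrees) about the center,
# then translate by (ty, tx) pixels; bilinear or nearest sampling, zero
# outside the frame.
warp_affine <- function(img, theta_deg, ty, tx,
                        interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  two_d <- is.matrix(img)
  if (two_d) img <- array(img, dim = c(dim(img), 1L))
  d <- dim(img); H <- d[1]; W <- d[2]
  th <- theta_deg * pi / 180
  ci <- (H + 1) / 2; cj <- (W + 1) / 2
  io <- matrix(seq_len(H), H, W) - ci - ty
  jo <- matrix(seq_len(W), H, W, byrow = TRUE) - cj - tx
  si <- cos(th) * io - sin(th) * jo + ci
  sj <- sin(th) * io + cos(th) * jo + cj
  out <- array(0, dim = d)
  if (interp == "nearest") {
    ri <- round(si); rj <- round(sj)
    ok <- ri >= 1 & ri <= H & rj >= 1 & rj <= W
    idx <- cbind(pmin(pmax(ri, 1), H)[ok], pmin(pmax(rj, 1), W)[ok])
    for (ch in seq_len(d[3])) {
      pl <- matrix(0, H, W)
      pl[ok] <- img[, , ch][idx]
      out[, , ch] <- pl
    }
  } else {
    i0 <- floor(si); j0 <- floor(sj)
    di <- si - i0; dj <- sj - j0
    for (ch in seq_len(d[3])) {
      pl <- img[, , ch]
      acc <- matrix(0, H, W)
      for (a in 0:1) for (b in 0:1) {
        ii <- i0 + a; jj <- j0 + b
        ok <- ii >= 1 & ii <= H & jj >= 1 & jj <= W
        w <- (if (a) di else 1 - di) * (if (b) dj else 1 - dj)
        contrib <- matrix(0, H, W)
        contrib[ok] <- pl[cbind(ii[ok], jj[ok])] * w[ok]
        acc <- acc + contrib
      }
      out[, , ch] <- acc
    }
  }
  if (two_d) out[, , 1] else out
}

resize_nearest <- function(img, Ho, Wo) {
  d <- dim(img)
  ri <- pmin(pmax(round((seq_len(Ho) - 0.5) * d[1] / Ho + 0.5), 1), d[1])
  ci <- pmin(pmax(round((seq_len(Wo) - 0.5) * d[2] / Wo + 0.5), 1), d[2])
  if (length(d) == 2L) img[ri, ci] else img[ri, ci, , drop = FALSE]
}

resize_image <- function(img, Ho, Wo) {
  two_d <- is.matrix(img)
  if (two_d) img <- array(img, dim = c(dim(img), 1L))
  out <- cpp_resize_bilinear(img, as.integer(Ho), as.integer(Wo))
  if (two_d) out[, , 1] else out
}

#' Paired data augmentation
#'
#' Flips (horizontal, vertical), translations (horizontal, vertical,
#' diagonal — the latter an equal shift along both axes), and rotation are
#' each applied with probability `augment_prob`, using one shared parameter
#' draw per transform so the B-mode, the elastogram and the mask receive
#' identical geometry. The sample is then resized to
#' `crop_size + resize_margin` and randomly cropped to `crop_size`.
#' Images are interpolated bilinearly, the mask nearest-neighbor. Draws
#' come from the current RNG state; seed the session for reproducibility.
#'
#' @param sample A `paired_sample`.
#' @param config A [train_config()].
#' @return The augmented `paired_sample`, with the applied transform
#'   parameters in `attr(, "transform")`.
#' @export
augment_pair <- function(sample, config = train_config()) {
  p <- config$augment_prob
  log <- list(hflip = FALSE, vflip = FALSE, tx = 0, ty = 0, theta = 0)
  bm <- sample$bmode; se <- sample$elastogram; mk <- sample$mask

  if (runif(1) < p) {
    log$hflip <- TRUE
    bm <- bm[, rev(seq_len(ncol(bm)))]
    se <- se[, rev(seq_len(ncol(se))), , drop = FALSE]
    mk <- mk[, rev(seq_len(ncol(mk)))]
  }
  if (runif(1) < p) {
    log$vflip <- TRUE
    bm <- bm[rev(seq_len(nrow(bm))), ]
    se <- se[rev(seq_len(nrow(se))), , , drop = FALSE]
    mk <- mk[rev(seq_len(nrow(mk))), ]
  }
  tx <- 0; ty <- 0
  if (runif(1) < p) tx <- tx + runif(1, -config$max_translate, config$max_translate)
  if (runif(1) < p) ty <- ty + runif(1, -config$max_translate, config$max_translate)
  if (runif(1) < p) {  # diagonal: equal shift on both axes
    dshift <- runif(1, -config$max_translate, config$max_translate)
    tx <- tx + dshift; ty <- ty + dshift
  }
  theta <- if (runif(1) < p) runif(1, -config$max_rotate, config$max_rotate) else 0
  log$tx <- tx; log$ty <- ty; log$theta <- theta
  if (theta != 0 || tx != 0 || ty != 0) {
    bm <- warp_affine(bm, theta, ty, tx, "bilinear")
    se <- warp_affine(se, theta, ty, tx, "bilinear")
    mk <- warp_affine(mk, theta, ty, tx, "nearest")
  }

  big <- config$crop_size + config$resize_margin
  bm <- resize_image(bm, big, big)
  se <- resize_image(se, big, big)
  mk <- resize_nearest(mk, big, big)
  if (p == 0 || config$resize_margin == 0L) {
    r0 <- config$resize_margin %/% 2L + 1L  # deterministic center crop
    c0 <- r0
  } else {
    r0 <- sample.int(config$resize_margin + 1L, 1L)
    c0 <- sample.int(config$resize_margin + 1L, 1L)
  }
  rs <- r0:(r0 + config$crop_size - 1L)
  cs <- c0:(c0 + config$crop_size - 1L)
  log$crop <- c(r0, c0)
  out <- structure(list(bmode = pmin(pmax(bm[rs, cs], 0), 1),
                        elastogram = pmin(pmax(se[rs, cs, , drop = FALSE], 0), 1),
                        mask = matrix(as.integer(mk[rs, cs] > 0.5),
                                      config$crop_size, config$crop_size),
                        score = sample$score, id = sample$id),
                   class = "paired_sample")
  attr(out, "transform") <- log
  out
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params, lr, beta1, beta2, eps = 1e-8) {
  list(params = params, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       m = lapply(params, function(p) p$value * 0),
       v = lapply(params, function(p) p$value * 0),
       t = 0L)
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * g
    opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * g^2
    p$value <- p$value - opt$lr * (opt$m[[i]] / c1) /
      (sqrt(opt$v[[i]] / c2) + opt$eps)
  }
  opt
}

# ---- one optimization step -------------------------------------------------

# Prepare the per-sample tensors used by both phases.
prepare_sample <- function(sample, roi_size) {
  roi_info <- extract_roi(sample$bmode, sample$mask, roi_size)
  w <- roi_info$window
  y_global <- elastogram_to_target(sample$elastogram)
  y_roi <- y_global[(w[["r0"]] + 1):w[["r1"]], (w[["c0"]] + 1):w[["c1"]], ,
                    drop = FALSE]
  list(x_global = bmode_to_input(sample$bmode), y_global = y_global,
       y_roi = y_roi, roi_info = roi_info, id = sample$id)
}

#' One adversarial training step
#'
#' Updates the two discriminators on real and detached-fake pairs, then the
#' generator on the adversarial + feature-matching + color objective.
#'
#' @param batch List of `paired_sample`s (already augmented/cropped to the
#'   network's global size).
#' @param gen Generator; `d1`, `d2` the global and ROI discriminators.
#' @param opt_g,opt_d1,opt_d2 Adam states from `adam_init()`.
#' @param weights A [loss_weights()].
#' @param kernel Color-loss blur kernel.
#' @return List with the updated optimizers and the scalar loss bundle
#'   (`adv_d1`, `adv_d2`, `adv_g`, `fm_d1`, `fm_d2`, `color`, `total_g`).
#' @export
train_step <- function(batch, gen, d1, d2, opt_g, opt_d1, opt_d2,
                       weights = loss_weights(),
                       kernel = gaussian_kernel(21L, 3)) {
  nb <- length(batch)
  prep <- lapply(batch, prepare_sample, roi_size = gen$config$roi_size)

  # One generator forward per sample; all losses are computed from this
  # snapshot, the fake is detached (by value) for the discriminator terms,
  # and the discriminators then the generator are stepped.
  ag_tape_start()
  d1_loss <- NULL; d2_loss <- NULL
  adv_g <- NULL; fm1 <- NULL; fm2 <- NULL; col <- NULL
  acc <- function(a, b) if (is.null(a)) b else ag_add(a, b)
  for (i in seq_len(nb)) {
    pr <- prep[[i]]
    fwd <- generator_forward(gen, pr$x_global, pr$roi_info)
    x_roi_in <- bmode_to_input(pr$roi_info$roi)
    r1 <- patch_discriminate(d1, pr$x_global, pr$y_global)
    r2 <- patch_discriminate(d2, x_roi_in, pr$y_roi)
    fd1 <- patch_discriminate(d1, pr$x_global, ag_value(fwd$global_out))
    fd2 <- patch_discriminate(d2, x_roi_in, ag_value(fwd$roi_out))
    d1_loss <- acc(d1_loss, adversarial_loss(r1$logits, fd1$logits,
                                             "discriminator"))
    d2_loss <- acc(d2_loss, adversarial_loss(r2$logits, fd2$logits,
                                             "discriminator"))
    f1 <- patch_discriminate(d1, pr$x_global, fwd$global_out)
    f2 <- patch_discriminate(d2, x_roi_in, fwd$roi_out)
    adv_g <- acc(adv_g, ag_add(adversarial_loss(NULL, f1$logits, "generator"),
                               adversarial_loss(NULL, f2$logits, "generator")))
    fm1 <- acc(fm1, feature_matching_loss(r1$features, f1$features))
    fm2 <- acc(fm2, feature_matching_loss(r2$features, f2$features))
    col <- acc(col, color_loss(fwd$global_out, pr$y_global, kernel))
  }
  d1_loss <- ag_scale(d1_loss, 1 / nb)
  d2_loss <- ag_scale(d2_loss, 1 / nb)
  adv_g <- ag_scale(adv_g, 1 / nb); fm1 <- ag_scale(fm1, 1 / nb)
  fm2 <- ag_scale(fm2, 1 / nb); col <- ag_scale(col, 1 / nb)
  total <- total_generator_loss(adv_g, fm1, fm2, col, weights)
  bundle <- c(adv_d1 = d1_loss$value, adv_d2 = d2_loss$value,
              adv_g = adv_g$value, fm_d1 = fm1$value, fm_d2 = fm2$value,
              color = col$value, total_g = total$value)
  if (any(!is.finite(bundle)))
    stop("non-finite loss on batch [", paste(vapply(prep, `[[`, "", "id"),
                                             collapse = ", "), "]")

  ag_zero_grad(opt_d1$params); ag_zero_grad(opt_d2$params)
  ag_backward(ag_add(d1_loss, d2_loss))
  opt_d1 <- adam_step(opt_d1)
  opt_d2 <- adam_step(opt_d2)

  ag_zero_grad(opt_g$params)
  ag_backward(total)
  opt_g <- adam_step(opt_g)
  ag_tape_start()  # release the graph
  list(opt_g = opt_g, opt_d1 = opt_d1, opt_d2 = opt_d2, bundle = bundle)
}

# ---- training loop ---------------------------------------------------------

derive_seed <- function(seed, k, salt) {
  as.integer((as.numeric(seed) + salt * (k + 1)) %% 2147483647)
}

#' Run adversarial training from a phantom manifest
#'
#' Epoch loop with seeded per-epoch shuffling, per-iteration paired
#' augmentation, discriminator-then-generator updates, a CSV loss log and
#' periodic checkpoints. Every random draw is derived from the training
#' seed and the iteration index, so a run — or a run resumed from a
#' checkpoint — is bit-reproducible on one CPU thread.
#'
#' @param manifest Manifest path from [generate_dataset()].
#' @param tconfig A [train_config()]; its `crop_size` must equal the
#'   network's `global_size`.
#' @param nconfig A [network_config()].
#' @param out_dir Output directory for the checkpoint and loss log.
#' @param weights A [loss_weights()].
#' @param resume_from Optional checkpoint path to resume from.
#' @param quiet Suppress progress messages.
#' @return List with `checkpoint` (final path), `log` (CSV path) and
#'   `losses` (data frame, one row per iteration).
#' @export
run_training <- function(manifest, tconfig = desk_train_config(),
                         nconfig = desk_network_config(), out_dir,
                         weights = loss_weights(), resume_from = NULL,
                         quiet = FALSE) {
  if (tconfig$crop_size != nconfig$global_size)
    stop("train crop_size must equal the network global_size")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  df <- read_manifest(manifest)
  samples <- list()
  for (i in seq_len(nrow(df))) {
    s <- tryCatch(load_sample(df[i, ]), error = function(e) {
      warning("skipping unreadable manifest row ", i, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(s)) samples[[length(samples) + 1L]] <- s
  }
  n <- length(samples)
  if (n == 0L) stop("no usable samples in manifest")
  if (n < tconfig$batch_size) stop("need at least batch_size samples")

  gen <- init_generator(modify_seed(nconfig, nconfig$seed))
  dcfg1 <- discriminator_config(base_channels = nconfig$base_channels,
                                seed = nconfig$seed + 1L)
  dcfg2 <- discriminator_config(base_channels = nconfig$base_channels,
                                seed = nconfig$seed + 2L)
  d1 <- init_discriminator(dcfg1)
  d2 <- init_discriminator(dcfg2)
  opt_g <- adam_init(collect_params(gen), tconfig$lr_g,
                     tconfig$adam_beta1, tconfig$adam_beta2)
  opt_d1 <- adam_init(collect_params(d1), tconfig$lr_d,
                      tconfig$adam_beta1, tconfig$adam_beta2)
  opt_d2 <- adam_init(collect_params(d2), tconfig$lr_d,
                      tconfig$adam_beta1, tconfig$adam_beta2)

  start_iter <- 0L
  log_path <- file.path(out_dir, "loss_log.csv")
  if (!is.null(resume_from)) {
    st <- load_checkpoint(resume_from)
    restore_params(gen, st$params$gen)
    restore_params(d1, st$params$d1)
    restore_params(d2, st$params$d2)
    opt_g <- restore_adam(opt_g, st$adam$g)
    opt_d1 <- restore_adam(opt_d1, st$adam$d1)
    opt_d2 <- restore_adam(opt_d2, st$adam$d2)
    start_iter <- st$iter
  } else if (file.exists(log_path)) {
    file.remove(log_path)
  }

  ipe <- max(1L, n %/% tconfig$batch_size)
  max_iters <- if (is.null(tconfig$max_iters)) tconfig$epochs * ipe
               else tconfig$max_iters
  kernel <- gaussian_kernel(min(21L, 2L * (tconfig$crop_size %/% 4L) + 1L), 3)
  rows <- vector("list", max_iters - start_iter)
  ckpt_path <- file.path(out_dir, "checkpoint.rds")

  iter <- start_iter
  while (iter < max_iters) {
    iter <- iter + 1L
    epoch <- (iter - 1L) %/% ipe
    pos <- (iter - 1L) %% ipe
    order <- with_seed(derive_seed(tconfig$seed, epoch, 77003), sample.int(n))
    idx <- order[(pos * tconfig$batch_size + 1L):
                 min((pos + 1L) * tconfig$batch_size, n)]
    batch <- with_seed(derive_seed(tconfig$seed, iter, 104729),
                       lapply(samples[idx], augment_pair, config = tconfig))
    st <- train_step(batch, gen, d1, d2, opt_g, opt_d1, opt_d2,
                     weights, kernel)
    opt_g <- st$opt_g; opt_d1 <- st$opt_d1; opt_d2 <- st$opt_d2
    row <- c(iteration = iter, st$bundle)
    rows[[iter - start_iter]] <- row
    write.table(as.data.frame(t(row)), log_path, sep = ",",
                col.names = !file.exists(log_path), row.names = FALSE,
                append = file.exists(log_path))
    if (!quiet && iter %% 20L == 0L)
      message(sprintf("iter %d/%d  total_g=%.3f  adv_d=%.3f", iter,
                      max_iters, row[["total_g"]],
                      row[["adv_d1"]] + row[["adv_d2"]]))
    if (iter %% tconfig$checkpoint_every == 0L || iter == max_iters)
      save_checkpoint(ckpt_path, gen, d1, d2, opt_g, opt_d1, opt_d2,
                      iter, tconfig)
  }
  losses <- as.data.frame(do.call(rbind, rows))
  list(checkpoint = ckpt_path, log = log_path, losses = losses)
}

modify_seed <- function(cfg, seed) { cfg$seed <- as.integer(seed); cfg }
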