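# Shared fixtures: small phantom configs, finite-difference harness, and a
# memoised desk-scale training run reused by the end-to-end checks.

desk_phantom_config <- function(seed = 1L, score = "random", size = 64L) {
  phantom_config(image_size = size, nodule_radius_range = c(6, 14),
                 target_score = score, seed = seed)
}

tiny_net_config <- function(seed = 11L) {
  network_config(base_channels = 4L, roi_size = 32L, global_size = 64L,
                 seed = seed)
}

# Central-difference gradient of a scalar-valued function at a few random
# coordinates, compared against an analytic gradient array.
fd_gradient_error <- function(fn, x, grad, n_probe = 10L, eps = 1e-5) {
  idx <- sample(length(x), min(n_probe, length(x)))
  num <- vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (fn(xp) - fn(xm)) / (2 * eps)
  }, 0)
  max(abs(num - grad[idx]))
}

# Desk-scale study conditions: 32 training phantoms at 64 px, base 8
# channels, 200 iterations, seed 42; 50 held-out phantoms (10 per score).
# Run once and cached for the end-to-end and determinism checks.
desk_run_cache <- new.env(parent = emptyenv())

get_desk_run <- function() {
  if (!is.null(desk_run_cache$res)) return(desk_run_cache$res)
  root <- file.path(tempdir(), "tsegan-desk-run")
  cfg <- phantom_config(image_size = 64L, nodule_radius_range = c(6, 14),
                        target_score = "random", seed = 42L)
  man_train <- generate_dataset(32L, cfg, file.path(root, "train"))
  held_cfg <- cfg; held_cfg$seed <- 4242L
  man_held <- generate_dataset(50L, held_cfg, file.path(root, "held"))
  res <- run_training(man_train, desk_train_config(seed = 42L, max_iters = 200L),
                      desk_network_config(seed = 42L),
                      file.path(root, "run"), quiet = TRUE)
  desk_run_cache$res <- list(train_manifest = man_train,
                             held_manifest = man_held,
                             run = res, root = root)
  desk_run_cache$res
}
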