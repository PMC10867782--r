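# Augmentation contracts, the optimization step, and the training loop
# (completion, logging, checkpointing, bit-identical resume).

test_that("augmentation at probability zero is only the deterministic resize/crop", {
  ph <- generate_phantom_pair(desk_phantom_config(seed = 71L, score = 2))
  cfg <- desk_train_config(71L)
  cfg$augment_prob <- 0
  set.seed(1)
  a <- augment_pair(ph, cfg)
  set.seed(2)
  b <- augment_pair(ph, cfg)
  expect_identical(a$bmode, b$bmode)       # no randomness left
  tr <- attr(a, "transform")
  expect_false(tr$hflip || tr$vflip)
  expect_equal(c(tr$tx, tr$ty, tr$theta), c(0, 0, 0))
  expect_equal(dim(a$bmode), c(64L, 64L))
})

test_that("sampled transform magnitudes respect the configured bounds", {
  ph <- generate_phantom_pair(desk_phantom_config(seed = 72L, score = 3))
  cfg <- train_config(crop_size = 64L, resize_margin = 8L, augment_prob = 1,
                      max_translate = 20, max_rotate = 15)
  set.seed(72)
  logs <- replicate(300, attr(augment_pair(ph, cfg), "transform"),
                    simplify = FALSE)
  # per-transform draws are bounded by 20 px; the diagonal adds one more
  # bounded draw per axis, so totals stay within 2 * 20
  expect_true(all(vapply(logs, function(l) abs(l$theta) <= 15, TRUE)))
  expect_true(all(vapply(logs, function(l)
    abs(l$tx) <= 40 && abs(l$ty) <= 40, TRUE)))
  thetas <- vapply(logs, `[[`, 0, "theta")
  expect_gt(max(abs(thetas)), 5)  # rotations actually drawn
})

test_that("the B-mode, elastogram and mask receive identical geometry", {
  # encode the B-mode into an elastogram channel; after augmentation the
  # shared-transform contract makes the two channels identical again
  ph <- generate_phantom_pair(desk_phantom_config(seed = 73L, score = 4))
  ph$elastogram[, , 2] <- ph$bmode
  cfg <- desk_train_config(73L)
  cfg$augment_prob <- 1
  set.seed(73)
  a <- augment_pair(ph, cfg)
  expect_equal(a$elastogram[, , 2], a$bmode, tolerance = 1e-12)
  # mask stays binary under nearest-neighbor interpolation
  expect_true(all(a$mask %in% c(0L, 1L)))
})

test_that("a training step updates parameters with the two-time-scale rates", {
  set.seed(74)
  gen <- init_generator(desk_network_config(74L))
  d1 <- init_discriminator(discriminator_config(base_channels = 8L, seed = 75L))
  d2 <- init_discriminator(discriminator_config(base_channels = 8L, seed = 76L))
  tcfg <- desk_train_config(74L)
  expect_equal(tcfg$lr_g, 2e-4)
  expect_equal(tcfg$lr_d, 1e-4)
  opt_g <- adam_init(collect_params(gen), tcfg$lr_g, tcfg$adam_beta1,
                     tcfg$adam_beta2)
  opt_d1 <- adam_init(collect_params(d1), tcfg$lr_d, tcfg$adam_beta1,
                      tcfg$adam_beta2)
  opt_d2 <- adam_init(collect_params(d2), tcfg$lr_d, tcfg$adam_beta1,
                      tcfg$adam_beta2)
  batch <- list(generate_phantom_pair(desk_phantom_config(seed = 77L, score = 5)),
                generate_phantom_pair(desk_phantom_config(seed = 78L, score = 1)))
  before_g <- vapply(collect_params(gen), function(p) sum(abs(p$value)), 0)
  st <- train_step(batch, gen, d1, d2, opt_g, opt_d1, opt_d2)
  expect_true(all(is.finite(st$bundle)))
  after_g <- vapply(collect_params(gen), function(p) sum(abs(p$value)), 0)
  expect_gt(max(abs(after_g - before_g)), 0)
  # loss-bundle identity: total = adv_g + alpha (fm1 + fm2) + beta color
  w <- loss_weights()
  expect_lt(abs(st$bundle[["total_g"]] -
                  (st$bundle[["adv_g"]] +
                     w$alpha * (st$bundle[["fm_d1"]] + st$bundle[["fm_d2"]]) +
                     w$beta * st$bundle[["color"]])), 1e-6)
})

test_that("training runs, logs, checkpoints, and resumes bit-identically", {
  root <- file.path(tempdir(), "train-small")
  man <- generate_dataset(6L, desk_phantom_config(seed = 79L), file.path(root, "ds"))
  tcfg <- desk_train_config(seed = 79L, max_iters = 6L)
  tcfg$checkpoint_every <- 3L
  ncfg <- desk_network_config(79L)

  res <- run_training(man, tcfg, ncfg, file.path(root, "runA"), quiet = TRUE)
  expect_true(file.exists(res$checkpoint))
  expect_true(file.exists(res$log))
  expect_equal(nrow(res$losses), 6L)
  expect_true(all(is.finite(as.matrix(res$losses))))

  # run only 3 iterations, then resume from its checkpoint for 3 more
  tcfg_half <- tcfg; tcfg_half$max_iters <- 3L
  resB1 <- run_training(man, tcfg_half, ncfg, file.path(root, "runB"),
                        quiet = TRUE)
  resB2 <- run_training(man, tcfg, ncfg, file.path(root, "runB2"),
                        resume_from = resB1$checkpoint, quiet = TRUE)
  expect_equal(unname(as.matrix(resB2$losses)),
               unname(as.matrix(res$losses[4:6, ])), tolerance = 0)

  expect_error(run_training(man, desk_train_config(), network_config(),
                            file.path(root, "bad")), "crop_size")
  unlink(root, recursive = TRUE)
})
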