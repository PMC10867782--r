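# Generator blocks: each reduction case is an oracle for the block's
# implementation, then shape/range/determinism contracts for the full model.

test_that("deformable convolution reduces to standard convolution at zero offset", {
  set.seed(21)
  x <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  W <- array(rnorm(3 * 3 * 4 * 4) * 0.3, c(3, 3, 4, 4))
  b <- rnorm(4)
  off0 <- array(0, c(16, 16, 18))
  ag_tape_start()
  d <- ag_deform_conv(ag_const(x), ag_const(W), ag_const(b), ag_const(off0),
                      stride = 1L, pad = 1L)
  s <- ag_conv2d(ag_const(x), ag_const(W), ag_const(b), stride = 1L, pad = 1L)
  expect_lt(max(abs(d$value - s$value)), 1e-5)
})

test_that("integer offsets equal convolution of the shifted input on interior pixels", {
  set.seed(22)
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  W <- array(rnorm(3 * 3 * 2 * 3) * 0.3, c(3, 3, 2, 3))
  b <- rnorm(3)
  # every tap shifted one column right: (drow, dcol) = (0, 1)
  off <- array(0, c(16, 16, 18))
  off[, , seq(2, 18, by = 2)] <- 1
  xs <- x
  xs[, 1:15, ] <- x[, 2:16, ]  # column-shifted input
  ag_tape_start()
  d <- ag_deform_conv(ag_const(x), ag_const(W), ag_const(b), ag_const(off),
                      stride = 1L, pad = 1L)
  s <- ag_conv2d(ag_const(xs), ag_const(W), ag_const(b), stride = 1L, pad = 1L)
  interior <- 2:14
  expect_lt(max(abs(d$value[interior, interior, ] - s$value[interior, interior, ])),
            1e-10)
})

test_that("constant input gives constant deformable output on interior pixels", {
  set.seed(23)
  W <- array(rnorm(3 * 3 * 2 * 2) * 0.3, c(3, 3, 2, 2))
  b <- rnorm(2)
  x <- array(0, c(12, 12, 2)); x[, , 1] <- 0.7; x[, , 2] <- -0.3
  off <- array(runif(12 * 12 * 18, -0.9, 0.9), c(12, 12, 18))
  ag_tape_start()
  d <- ag_deform_conv(ag_const(x), ag_const(W), ag_const(b), ag_const(off),
                      stride = 1L, pad = 1L)
  expected <- 0.7 * apply(W[, , 1, ], 3, sum) - 0.3 * apply(W[, , 2, ], 3, sum) + b
  for (o in 1:2)
    expect_lt(max(abs(d$value[3:10, 3:10, o] - expected[o])), 1e-10)
})

test_that("residual blocks with zero weights are the identity map", {
  set.seed(24)
  blk <- res_block(6L)
  for (p in collect_params(blk)) p$value <- p$value * 0
  x <- array(rnorm(10 * 10 * 6), c(10, 10, 6))
  ag_tape_start()
  out <- fw_res(blk, ag_const(x))
  expect_equal(out$value, x, tolerance = 1e-12)
})

test_that("SPADE standardization and identity modulation behave as specified", {
  set.seed(25)
  blk <- spade_block(5L, 8L)
  x <- array(rnorm(12 * 12 * 5, mean = 2, sd = 3), c(12, 12, 5))
  skip <- array(rnorm(12 * 12 * 5), c(12, 12, 5))
  raw <- array(rnorm(12 * 12 * 3), c(12, 12, 3))
  ag_tape_start()
  res <- fw_spade(blk, ag_const(x), ag_const(skip), ag_const(raw))
  norm <- res$normalized$value
  for (ch in 1:5) {
    expect_lt(abs(mean(norm[, , ch])), 1e-5)
    expect_lt(abs(mean(norm[, , ch]^2) - mean(norm[, , ch])^2 - 1), 1e-4)
  }
  # zeroed modulation net -> (1 + 0) * xhat + 0: denorm equals normalized
  for (nm in c("m1", "mg", "mb")) {
    blk[[nm]]$W$value <- blk[[nm]]$W$value * 0
    blk[[nm]]$b$value <- blk[[nm]]$b$value * 0
  }
  ag_tape_start()
  res0 <- fw_spade(blk, ag_const(x), ag_const(skip), ag_const(raw))
  expect_equal(res0$denorm$value, res0$normalized$value, tolerance = 1e-12)
})

test_that("SPADE output responds to the raw conditioning image", {
  set.seed(26)
  blk <- spade_block(4L, 7L)
  x <- array(rnorm(10 * 10 * 4), c(10, 10, 4))
  skip <- array(rnorm(10 * 10 * 4), c(10, 10, 4))
  raw1 <- array(rnorm(10 * 10 * 3), c(10, 10, 3))
  raw2 <- raw1 + 0.5
  ag_tape_start()
  o1 <- fw_spade(blk, ag_const(x), ag_const(skip), ag_const(raw1))$out$value
  o2 <- fw_spade(blk, ag_const(x), ag_const(skip), ag_const(raw2))$out$value
  expect_gt(max(abs(o1 - o2)), 0)
})

test_that("spatial attention masks are sigmoid-bounded with the forced 0.5 case", {
  set.seed(27)
  sa <- sa_module()
  x <- array(rnorm(14 * 14 * 6), c(14, 14, 6))
  ag_tape_start()
  res <- fw_sa(sa, ag_const(x))
  expect_true(all(res$mask$value > 0 & res$mask$value < 1))
  expect_equal(dim(res$out$value), dim(x))
  sa$conv$W$value <- sa$conv$W$value * 0
  sa$conv$b$value <- sa$conv$b$value * 0
  ag_tape_start()
  res0 <- fw_sa(sa, ag_const(x))
  expect_equal(res0$out$value, 0.5 * x, tolerance = 1e-12)
})

test_that("content revisor: n masks, attention simplex, exact background case, range", {
  set.seed(28)
  gen <- init_generator(tiny_net_config())
  b <- gen$config$base_channels
  m <- array(rnorm(64 * 64 * b), c(64, 64, b))
  x <- array(runif(64 * 64 * 3, -1, 1), c(64, 64, 3))
  ag_tape_start()
  res <- content_revisor(gen, ag_const(m), ag_const(x))
  expect_length(res$content_masks, 3L)        # n = 4 -> 3 foreground masks
  expect_length(res$attention$value, 4L)
  expect_lt(abs(sum(res$attention$value) - 1), 1e-6)
  expect_true(all(res$out$value >= -1 & res$out$value <= 1))

  # force the background weight to 1: output must be the input exactly
  gen$revisor$fc$W$value <- gen$revisor$fc$W$value * 0
  gen$revisor$fc$b$value <- c(-800, -800, -800, 800)
  ag_tape_start()
  res_bg <- content_revisor(gen, ag_const(m), ag_const(x))
  expect_identical(res_bg$out$value, x)
  expect_error(network_config(n_groups = 1L), "at least 2")
})

test_that("local generator produces the documented shapes", {
  set.seed(29)
  gen <- init_generator(desk_network_config(3L))  # base 8, ROI 32
  roi <- array(runif(32 * 32 * 3, -1, 1), c(32, 32, 3))
  ag_tape_start()
  loc <- run_local_generator(gen, ag_const(roi))
  expect_equal(dim(loc$out$value), c(32L, 32L, 3L))
  expect_true(all(abs(loc$out$value) < 1))
  expect_equal(dim(loc$fusion_features$value), c(32L, 32L, 8L))
  expect_error(run_local_generator(gen, ag_const(roi[1:16, 1:16, ])), "roi_size")
  # encoder bottleneck shape: 128 px ROI, base 8 -> 32 x 32 x 32 after two
  # downsamples (checked on the desk profile scaled by the same factors)
  expect_equal(dim(ag_value(loc$fusion_features))[1] / 1L, gen$config$roi_size)
})

test_that("feature fusion embeds the pooled local features at the scaled ROI window", {
  set.seed(30)
  gen <- init_generator(desk_network_config(4L))
  b <- gen$config$base_channels
  glob <- array(rnorm(16 * 16 * 4 * b), c(16, 16, 4 * b))  # 64/4 bottleneck
  fus <- array(rnorm(32 * 32 * b), c(32, 32, b))
  ag_tape_start()
  # zero local features: fusion is the identity on the global features
  z <- fuse_features(gen, ag_const(glob), ag_const(fus * 0), c(r0 = 16, c0 = 24))
  expect_identical(z$value, glob)
  f <- fuse_features(gen, ag_const(glob), ag_const(fus), c(r0 = 16, c0 = 24))
  delta <- f$value - glob
  rows <- 1 + 16 %/% 4; cols <- 1 + 24 %/% 4
  expect_true(all(delta[-(rows:(rows + 7)), , ] == 0))
  expect_true(all(delta[, -(cols:(cols + 7)), ] == 0))
  expect_equal(dim(delta[rows:(rows + 7), cols:(cols + 7), ]), c(8L, 8L, 4L * b))
  expect_error(fuse_features(gen, ag_const(glob), ag_const(fus),
                             c(r0 = 60, c0 = 0)), "outside")
})

test_that("run_generator yields bounded, deterministic, correctly-shaped outputs", {
  ph <- generate_phantom_pair(desk_phantom_config(seed = 31L, score = 4))
  gen <- init_generator(desk_network_config(31L))
  out1 <- run_generator(gen, ph$bmode, ph$mask)
  expect_equal(dim(out1$global_out), c(64L, 64L, 3L))
  expect_equal(dim(out1$roi_out), c(32L, 32L, 3L))
  expect_true(all(is.finite(out1$global_out)) && all(is.finite(out1$roi_out)))
  expect_true(all(abs(out1$global_out) <= 1) && all(abs(out1$roi_out) <= 1))
  expect_equal(length(out1$diagnostics$content_masks), 3L)
  out2 <- run_generator(gen, ph$bmode, ph$mask)
  expect_identical(out1$global_out, out2$global_out)
  expect_error(run_generator(gen, ph$bmode[1:32, 1:32], ph$mask), "global_size")
})

test_that("a loss on both outputs reaches every submodule (no dead branches)", {
  ph <- generate_phantom_pair(desk_phantom_config(seed = 32L, score = 5))
  gen <- init_generator(desk_network_config(32L))
  roi_info <- extract_roi(ph$bmode, ph$mask, gen$config$roi_size)
  ag_tape_start()
  fwd <- generator_forward(gen, bmode_to_input(ph$bmode), roi_info)
  loss <- ag_add(ag_sum(ag_square(fwd$global_out)),
                 ag_sum(ag_square(fwd$roi_out)))
  ag_zero_grad(collect_params(gen))
  ag_backward(loss)
  groups <- list(local_enc0 = gen$local$enc0, local_down = gen$local$down,
                 local_fusion = gen$local$fusion, local_up = gen$local$up,
                 local_out = gen$local$out, global_enc0 = gen$global$enc0,
                 global_sa = gen$global$sa, global_down = gen$global$down,
                 global_proj = gen$global$proj,
                 global_fusion = gen$global$fusion, global_up = gen$global$up,
                 revisor = gen$revisor)
  for (nm in names(groups)) {
    gnorm <- sum(vapply(collect_params(groups[[nm]]), function(p)
      if (is.null(p$grad)) 0 else sum(p$grad^2), 0))
    expect_gt(gnorm, 0)
  }
  # offset-prediction convolutions receive gradient too
  off_grad <- sum(gen$local$enc0$off$W$grad^2)
  expect_gt(off_grad, 0)
})

test_that("the desk profile stays under one million parameters", {
  gen <- init_generator(desk_network_config(1L))
  d1 <- init_discriminator(discriminator_config(base_channels = 8L, seed = 2L))
  expect_lt(n_parameters(gen), 1e6)
  expect_lt(n_parameters(gen) + 2 * n_parameters(d1), 1e6)
})
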