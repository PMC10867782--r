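# Synthetic phantom generator: determinism, Rago-band fidelity,
# registration, ROI extraction, segmentation fallback and dataset output.

test_that("phantom configuration rejects invalid settings", {
  expect_error(phantom_config(image_size = 32), "at least 64")
  expect_error(phantom_config(image_size = 64, nodule_radius_range = c(20, 60)),
               "twice the maximum")
  expect_error(phantom_config(target_score = 7), "1..5")
  expect_error(phantom_config(spot_density = 1.5), "0, 1")
})

test_that("phantoms are a pure function of their config", {
  cfg <- desk_phantom_config(seed = 5L, score = 3)
  a <- generate_phantom_pair(cfg)
  b <- generate_phantom_pair(cfg)
  expect_identical(a, b)
  # and the generator does not disturb the session RNG
  set.seed(1); before <- .Random.seed
  invisible(generate_phantom_pair(cfg))
  expect_identical(.Random.seed, before)
})

test_that("nodule blue fraction lands in the designed band for every score", {
  bands <- rago_bands()
  for (score in 1:5) {
    for (seed in 1:10) {
      ph <- generate_phantom_pair(desk_phantom_config(seed = seed, score = score))
      r <- blue_green_ratio(ph$elastogram, ph$mask)
      band <- bands[[as.character(score)]]
      expect_gte(r, band[1])
      expect_lte(r, band[2])
    }
  }
  # spec'd spot checks
  ph5 <- generate_phantom_pair(phantom_config(target_score = 5, seed = 1))
  expect_gte(blue_green_ratio(ph5$elastogram, ph5$mask), 0.95)
  ph1 <- generate_phantom_pair(phantom_config(target_score = 1, seed = 7))
  expect_lte(blue_green_ratio(ph1$elastogram, ph1$mask), 0.05)
})

test_that("mask is a single component and blue core registers with the nodule", {
  for (seed in 1:8) {
    ph <- generate_phantom_pair(desk_phantom_config(seed = 200 + seed))
    lab <- EBImage::bwlabel(EBImage::Image(ph$mask))
    expect_equal(max(EBImage::imageData(lab)), 1)

    sel <- ph$mask == 1
    rch <- ph$elastogram[, , 1]; gch <- ph$elastogram[, , 2]
    bch <- ph$elastogram[, , 3]
    blue <- sel & bch > rch & bch > gch
    m_cent <- colMeans(which(sel, arr.ind = TRUE))
    b_cent <- colMeans(which(blue, arr.ind = TRUE))
    expect_lt(sqrt(sum((m_cent - b_cent)^2)), 2)
  }
})

test_that("blue_green_ratio counts strict blue dominance", {
  mk <- matrix(1L, 2, 2)
  pure_blue <- array(rep(c(0, 0, 1), each = 4), dim = c(2, 2, 3))
  expect_equal(blue_green_ratio(pure_blue, mk), 1)
  pure_green <- array(rep(c(0, 1, 0), each = 4), dim = c(2, 2, 3))
  expect_equal(blue_green_ratio(pure_green, mk), 0)
  half <- pure_green
  half[1, , 3] <- 2  # two of four pixels blue-dominant
  expect_equal(blue_green_ratio(half, mk), 0.5)
  expect_error(blue_green_ratio(pure_blue, matrix(0L, 2, 2)), "empty")
  expect_error(blue_green_ratio(pure_blue, matrix(1L, 3, 3)), "shapes")
})

test_that("proxy score thresholds align with the design bands", {
  expect_equal(proxy_rago_score(0.02), 1L)
  expect_equal(proxy_rago_score(0.25), 2L)
  expect_equal(proxy_rago_score(0.5), 3L)
  expect_equal(proxy_rago_score(0.75), 4L)
  expect_equal(proxy_rago_score(0.97), 5L)
})

test_that("ROI extraction centers on the mask centroid and clamps at borders", {
  img <- matrix(runif(256 * 256), 256, 256)
  mk <- matrix(0L, 256, 256); mk[121:136, 121:136] <- 1L  # centroid at center
  res <- extract_roi(img, mk, 128L)
  expect_equal(unname(res$window), c(64, 192, 64, 192))
  expect_equal(dim(res$roi), c(128L, 128L))
  expect_equal(res$roi, img[65:192, 65:192])

  mk2 <- matrix(0L, 256, 256); mk2[5:7, 5:7] <- 1L  # centroid near (5,5)
  res2 <- extract_roi(img, mk2, 128L)
  expect_equal(unname(res2$window), c(0, 128, 0, 128))

  expect_warning(res3 <- extract_roi(img, matrix(0L, 256, 256), 128L), "empty")
  expect_equal(unname(res3$window), c(64, 192, 64, 192))
  expect_error(extract_roi(matrix(0, 64, 64), mk[1:64, 1:64], 128L), "smaller")
})

test_that("naive segmentation recovers dark discs and overlaps phantom nodules", {
  # clean disc on a bright field
  img <- matrix(0.9, 96, 96)
  ii <- matrix(seq_len(96), 96, 96); jj <- t(ii)
  disc <- (ii - 48)^2 + (jj - 48)^2 <= 18^2
  img[disc] <- 0.2
  seg <- naive_segment(img)
  inter <- sum(seg == 1 & disc); uni <- sum(seg == 1 | disc)
  expect_gt(inter / uni, 0.8)

  expect_error(naive_segment(matrix(0.5, 32, 32)), "constant")

  ious <- vapply(1:20, function(seed) {
    ph <- generate_phantom_pair(phantom_config(image_size = 128L,
                                               nodule_radius_range = c(12, 28),
                                               target_score = 4,
                                               seed = 300 + seed))
    seg <- naive_segment(ph$bmode)
    sum(seg == 1 & ph$mask == 1) / sum(seg == 1 | ph$mask == 1)
  }, 0)
  expect_gte(min(ious), 0.3)
})

test_that("generate_dataset writes balanced, reproducible PNG triplets", {
  out1 <- file.path(tempdir(), "ds1"); out2 <- file.path(tempdir(), "ds2")
  cfg <- desk_phantom_config(seed = 77L)
  man <- generate_dataset(10L, cfg, out1)
  df <- read_manifest(man)
  expect_equal(nrow(df), 10L)
  expect_equal(length(list.files(out1, pattern = "\\.png$")), 30L)
  expect_equal(as.integer(table(df$score)), rep(2L, 5))  # balanced scores

  man2 <- generate_dataset(10L, cfg, out2)
  sums1 <- unname(tools::md5sum(sort(list.files(out1, full.names = TRUE))))
  sums2 <- unname(tools::md5sum(sort(list.files(out2, full.names = TRUE))))
  expect_identical(sums1, sums2)

  s <- load_sample(df[1, ])
  expect_s3_class(s, "paired_sample")
  expect_equal(dim(s$bmode), c(64L, 64L))
  expect_equal(dim(s$elastogram), c(64L, 64L, 3L))
  expect_true(all(s$mask %in% c(0L, 1L)))
  unlink(c(out1, out2), recursive = TRUE)
})
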