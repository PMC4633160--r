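test_that("ground truth is reproducible from its seed", {
  lay <- plate_layout(10, 15)
  a <- sample_ground_truth(lay, seed = 99)
  b <- sample_ground_truth(lay, seed = 99)
  expect_identical(a, b)
  expect_false(identical(a$positions,
                         sample_ground_truth(lay, seed = 100)$positions))
})

test_that("occupancy follows the deposition viability", {
  lay <- make_layout(3750, 1.5)
  band <- 4 * sqrt(3750 * 0.94 * 0.06)   # 4 binomial SDs around 3525
  for (s in 1:5) {
    gt <- sample_ground_truth(lay, viability = 0.94, seed = s)
    occ <- sum(gt$positions$occupancy != "empty")
    expect_lt(abs(occ - 3525), band)
  }
  # law of large numbers at 10^4 positions
  gt <- sample_ground_truth(plate_layout(100, 100), viability = 0.94, seed = 1)
  expect_equal(mean(gt$positions$occupancy != "empty"), 0.94, tolerance = 0.01)
})

test_that("a 0.5% spike yields ~18.75 red singles per 3750-point plate", {
  lay <- make_layout(3750, 1.5)
  counts <- vapply(1:8, function(s) {
    gt <- sample_ground_truth(lay, viability = 1, doublet_rate = 0,
                              variant_mix = c(x5_FLuc = 0.995, x5_FLuc_red = 0.005),
                              seed = s)
    sum(gt$positions$variant1 == "x5_FLuc_red")
  }, numeric(1))
  se <- sqrt(3750 * 0.005 * 0.995 / 8)
  expect_lt(abs(mean(counts) - 18.75), 4 * se)
})

test_that("half of 1:1-mix doublets are two-coloured", {
  lay <- plate_layout(100, 100)
  frac <- vapply(1:6, function(s) {
    gt <- sample_ground_truth(lay, viability = 1, doublet_rate = 0.1,
                              variant_mix = c(a = 0.5, b = 0.5), seed = s)
    p <- gt$positions
    dbl <- p$occupancy == "double"
    sum(dbl & p$variant1 != p$variant2) / sum(p$occupancy != "empty")
  }, numeric(1))
  expect_equal(mean(frac), 0.05, tolerance = 0.1)
})

test_that("brightness calibration reproduces the 0.14 +/- 0.03 distribution", {
  gt <- sample_ground_truth(plate_layout(100, 100), viability = 1,
                            doublet_rate = 0, seed = 5)
  b <- gt$positions$b1
  n <- length(b)
  expect_lt(abs(mean(b) - 0.14), 3 * 0.03 / sqrt(n))
  expect_lt(abs(stats::sd(b) - 0.03), 3 * 0.03 / sqrt(2 * n))
  expect_true(all(b > 0))
})

test_that("variant mix must sum to one", {
  expect_error(sample_ground_truth(plate_layout(2, 2),
                                   variant_mix = c(a = 0.6, b = 0.5)),
               "sum to 1")
})

test_that("colony radius shrinks with matrix density", {
  expect_equal(colony_radius_model(44, r_ref_px = 6, d_ref = 44), 6)
  d <- c(7, 20, 44, 100, 195)
  r <- colony_radius_model(d)
  expect_true(all(diff(r) < 0))
  expect_equal(colony_radius_model(d, alpha = 0), rep(6, 5))
  expect_error(colony_radius_model(-1), "positive")
})

test_that("rendered signal is conserved per band with noise and blur off", {
  lay <- plate_layout(5, 8)
  gt <- sample_ground_truth(lay, viability = 1, doublet_rate = 0,
                            pos_jitter_um = 0, seed = 3)
  r <- render_plate(gt, optics = noise_free_optics())
  for (b in names(r$images)) {
    expected <- sum(gt$positions$brightness * r$band_fractions["x5_FLuc", b])
    expect_equal(sum(r$images[[b]]), expected, tolerance = 0.005)
  }
})

test_that("doublet discs carry the summed spectra of both members", {
  lay <- plate_layout(2, 3)
  gt <- sample_ground_truth(lay, viability = 1, doublet_rate = 1,
                            variant_mix = c(x5_FLuc = 0.5, x5_FLuc_red = 0.5),
                            pos_jitter_um = 0, seed = 8)
  r <- render_plate(gt, optics = noise_free_optics())
  p <- gt$positions
  fr <- r$band_fractions
  for (b in names(r$images)) {
    expected <- sum(p$b1 * fr[p$variant1, b] + p$b2 * fr[p$variant2, b])
    expect_equal(sum(r$images[[b]]), expected, tolerance = 0.005)
  }
})

test_that("red-shifted colonies flip the 550-600 / 590-640 band ordering", {
  lay <- plate_layout(1, 2)
  gt <- sample_ground_truth(lay, viability = 1, doublet_rate = 0,
                            variant_mix = c(x5_FLuc = 0.5, x5_FLuc_red = 0.5),
                            pos_jitter_um = 0, seed = 14)
  # force one of each variant
  gt$positions$variant1 <- c("x5_FLuc", "x5_FLuc_red")
  r <- render_plate(gt, optics = noise_free_optics())
  green <- r$images[["550-600"]]; red <- r$images[["590-640"]]
  w <- ncol(green) %/% 2
  left <- seq_len(w)                       # x5_FLuc colony
  expect_gt(sum(green[, left]), sum(red[, left]))
  expect_gt(sum(red[, -left]), sum(green[, -left]))
})

test_that("an empty plate renders as background plus noise only", {
  lay <- plate_layout(4, 6)
  gt <- sample_ground_truth(lay, viability = 0, seed = 2)
  opt <- optics_model()
  r <- render_plate(gt, optics = opt, seed = 5)
  m <- r$images[[2]]
  expect_equal(mean(m), opt$background_level, tolerance = 0.01)
  expect_lt(stats::sd(m), 3 * sqrt(opt$background_level / opt$photons_per_unit +
                                     opt$read_noise_sd^2))
  expect_equal(nrow(r$truth), 0)
})

test_that("band images round-trip through 16-bit TIFF and PNG", {
  fx <- render_spiked_fixture(seed = 21, n_rows = 4, n_cols = 6)
  dir <- withr::local_tempdir()
  write_plate_images(fx$rendered, dir, format = "tiff")
  imgs <- read_plate_images(dir)
  expect_setequal(names(imgs), names(fx$rendered$images))
  expect_lt(max(abs(imgs[["550-600"]] - fx$rendered$images[["550-600"]])),
            1 / 65535)
  write_plate_images(fx$rendered, dir, prefix = "p8", format = "png")
  expect_length(read_plate_images(dir, prefix = "p8"), 6)
  expect_error(read_plate_images(dir, prefix = "nothere"), "no band images")
})
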