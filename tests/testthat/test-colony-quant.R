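test_that("a blank image yields zero components", {
  img <- matrix(0.01, 60, 80)
  seg <- segment_colonies(img)
  expect_equal(seg$n, 0)
})

test_that("well-separated colonies are each one component", {
  fx <- render_spiked_fixture(seed = 31)
  seg <- segment_colonies(max_projection(fx$rendered$images))
  expect_equal(seg$n, nrow(fx$rendered$truth))
  expect_length(seg$merged, 0)
})

test_that("segmentation only uses relative intensities", {
  fx <- render_spiked_fixture(seed = 32, optics = optics_model())
  img <- max_projection(fx$rendered$images)
  a <- segment_colonies(img)
  b <- segment_colonies(img * 7.3 + 0.2)
  expect_equal(a$n, b$n)
  expect_equal(a$labels, b$labels)
})

test_that("touching colonies merge into one flagged component", {
  img <- matrix(0, 80, 120)
  for (cx in seq(15, 105, by = 15)) img <- draw_disc(img, 20, cx, 4)
  img <- draw_disc(img, 60, 40, 4)          # pair closer than 2 radii
  img <- draw_disc(img, 60, 46, 4)
  seg <- segment_colonies(img, min_area_px = 4)
  expect_equal(seg$n, 8)                     # 7 singles + 1 fused pair
  expect_length(seg$merged, 1)
  areas <- tabulate(seg$labels[seg$labels > 0])
  expect_equal(which.max(areas), seg$merged)
})

test_that("non-2D input is rejected", {
  expect_error(segment_colonies(array(0, c(4, 4, 2))), "2-D")
  expect_error(segment_colonies(1:10), "2-D")
})

test_that("a rasterised disc's area is close to pi r^2", {
  for (r in c(3, 5, 9)) {
    img <- draw_disc(matrix(0, 64, 64), 32, 32, r)
    seg <- segment_colonies(img, min_area_px = 1)
    rec <- measure_colonies(seg, list(b = img), background = "global")
    expect_equal(rec$area_px, pi * r^2, tolerance = 0.05)
  }
})

test_that("background subtraction removes a uniform offset", {
  fx <- render_spiked_fixture(seed = 33)
  seg <- segment_colonies(max_projection(fx$rendered$images))
  base <- measure_colonies(seg, fx$rendered$images)
  up <- measure_colonies(seg, lapply(fx$rendered$images, `+`, 0.07))
  expect_equal(intensity_matrix(up), intensity_matrix(base), tolerance = 1e-10)
  gl <- measure_colonies(seg, lapply(fx$rendered$images, `+`, 0.07),
                         background = "global")
  expect_equal(intensity_matrix(gl), intensity_matrix(base), tolerance = 1e-10)
})

test_that("noise-free photometry recovers brightness x band fraction", {
  fx <- render_spiked_fixture(seed = 34)
  r <- fx$rendered
  seg <- segment_colonies(max_projection(r$images))
  rec <- measure_colonies(seg, r$images)
  asg <- assign_to_grid(rec, fx$layout, pixel_um = 50)
  rec <- asg$records
  tt <- r$truth
  key_rec <- paste(rec$row, rec$col)
  key_tt <- paste(tt$row, tt$col)
  im <- intensity_matrix(rec)
  for (b in c("550-600", "590-640")) {
    expected <- unname(tt$brightness * r$band_fractions[tt$variant, b])
    expect_equal(unname(im[match(key_tt, key_rec), b]), expected,
                 tolerance = 0.01)
  }
})

test_that("noise-free plates assign 100% to the correct lattice nodes", {
  fx <- render_spiked_fixture(seed = 35)
  q <- quantify_plate(fx$rendered)
  rec <- q$records
  expect_true(all(!is.na(rec$row)))
  expect_setequal(paste(rec$row, rec$col),
                  paste(fx$rendered$truth$row, fx$rendered$truth$col))
  # bookkeeping identity: unoccupied nodes complement the truth
  expect_equal(nrow(q$unoccupied),
               n_positions(fx$layout) - nrow(fx$rendered$truth))
  expect_equal(q$qc$n_assigned, nrow(fx$rendered$truth))
})

test_that("grid assignment tolerates centroid jitter of pitch/10", {
  lay <- plate_layout(12, 18, pitch_um = 500)
  gt <- sample_ground_truth(lay, viability = 0.94, doublet_rate = 0,
                            pos_jitter_um = 50, seed = 41)  # pitch/10
  r <- render_plate(gt, optics = noise_free_optics())
  q <- quantify_plate(r)
  rec <- q$records
  correct <- sum(paste(rec$row, rec$col) %in%
                   paste(r$truth$row, r$truth$col))
  expect_gte(correct / nrow(rec), 0.99)
})

test_that("grid fitting fails loudly on non-lattice centroids", {
  set.seed(7)
  rec <- data.frame(label = 1:40, centroid_x = runif(40, 0, 300),
                    centroid_y = runif(40, 0, 300), area_px = 20, flag = "",
                    row = NA_integer_, col = NA_integer_, I_b = 1)
  expect_error(assign_to_grid(rec, plate_layout(10, 10, pitch_um = 500), 50),
               "grid fit failed")
  expect_error(assign_to_grid(rec[1:3, ], plate_layout(10, 10), 50),
               "at least 4")
})

test_that("simulate -> quantify round trip ranks brightness correctly", {
  fx <- render_spiked_fixture(seed = 36)
  q <- quantify_plate(fx$rendered)
  rec <- q$records
  tt <- fx$rendered$truth
  m <- match(paste(tt$row, tt$col), paste(rec$row, rec$col))
  expect_true(all(!is.na(m)))
  total <- rowSums(intensity_matrix(rec))[m]
  rho <- stats::cor(total, tt$brightness, method = "spearman")
  expect_gt(rho, 0.99)
})

test_that("measured mean colony area falls as matrix density rises", {
  # pitch chosen so lattice density matches the target colonies/cm2
  dens <- c(7, 44, 100, 195)
  areas <- vapply(dens, function(d) {
    pitch <- 10000 / sqrt(d)
    lay <- plate_layout(6, 9, pitch_um = pitch)
    gt <- sample_ground_truth(lay, viability = 1, doublet_rate = 0,
                              pos_jitter_um = 0, seed = 50 + d)
    q <- quantify_plate(render_plate(gt, optics = noise_free_optics()))
    mean(q$records$area_px)
  }, numeric(1))
  expect_true(all(diff(areas) < 0))
})

test_that("colony CSV round-trips", {
  fx <- render_spiked_fixture(seed = 37, n_rows = 5, n_cols = 8)
  q <- quantify_plate(fx$rendered)
  p <- withr::local_tempfile(fileext = ".csv")
  write_colonies_csv(q$records, p)
  back <- read_colonies_csv(p)
  expect_equal(intensity_matrix(back), intensity_matrix(q$records))
  expect_equal(back$row, q$records$row)
})
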