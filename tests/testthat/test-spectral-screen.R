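test_that("spectra normalise to unit maximum", {
  expect_equal(normalize_spectrum(c(2, 4, 8, 4, 2, 1)),
               c(0.25, 0.5, 1, 0.5, 0.25, 0.125))
  x <- c(0.3, 1.1, 0.7, 0.2, 0.05, 0.01)
  expect_equal(normalize_spectrum(x * 37), normalize_spectrum(x))
  expect_error(normalize_spectrum(rep(0, 6)), "no signal")
})

test_that("classification recovers a reference exactly and scale-invariantly", {
  refs <- reference_spectra()
  cl <- classify_spectrum(refs["x5_FLuc_red", ], refs)
  expect_equal(cl$variant, "x5_FLuc_red")
  expect_equal(cl$distance, 0)
  expect_true(cl$confident)
  # raw intensities scaled by any constant give the same call
  raw <- band_fractions(emission_spectrum(615))
  for (c0 in c(0.01, 1, 250)) {
    cl2 <- classify_spectrum(normalize_spectrum(raw * c0), refs)
    expect_equal(cl2$variant, "x5_FLuc_red")
    expect_true(cl2$confident)
  }
  expect_error(classify_spectrum(c(1, 0.5), refs), "length")
})

test_that("a spectrum midway between the references is not confident", {
  refs <- reference_spectra()
  mid <- normalize_spectrum((refs[1, ] + refs[2, ]) / 2)
  cl <- classify_spectrum(mid, refs)
  expect_false(cl$confident)
})

test_that("red_ratio rises strictly as the peak shifts 550 -> 615 nm", {
  refs <- reference_spectra()
  peaks <- seq(550, 615, by = 5)
  ratios <- vapply(peaks, function(p) {
    classify_spectrum(normalize_spectrum(band_fractions(emission_spectrum(p))),
                      refs)$red_ratio
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("plate calling finds exactly the spiked colonies, noise off", {
  fx <- render_spiked_fixture(seed = 61)
  q <- quantify_plate(fx$rendered)
  calls <- call_plate(q$records, reference_spectra(), fx$layout,
                      majority = "x5_FLuc")
  tt <- fx$rendered$truth
  spiked <- tt[tt$variant == "x5_FLuc_red", ]
  expect_gt(nrow(spiked), 0)
  expect_setequal(paste(calls$hits$row, calls$hits$col),
                  paste(spiked$row, spiked$col))
  expect_true(all(calls$hits$variant == "x5_FLuc_red"))
  expect_true(all(calls$calls$confident))
})

test_that("an all-majority plate yields no hits", {
  fx <- render_spiked_fixture(seed = 62, spike = 0)
  q <- quantify_plate(fx$rendered)
  calls <- call_plate(q$records, reference_spectra(), fx$layout,
                      majority = "x5_FLuc")
  expect_equal(nrow(calls$hits), 0)
  expect_true(all(calls$calls$variant == "x5_FLuc"))
})

test_that("calling is invariant to per-colony brightness", {
  fx <- render_spiked_fixture(seed = 63)
  q <- quantify_plate(fx$rendered)
  rec2 <- q$records
  icols <- grep("^I_", names(rec2))
  set.seed(1)
  rec2[icols] <- rec2[icols] * runif(nrow(rec2), 0.2, 5)  # per-colony scale
  a <- call_plate(q$records, reference_spectra(), majority = "x5_FLuc")
  b <- call_plate(rec2, reference_spectra(), majority = "x5_FLuc")
  expect_equal(b$calls$variant, a$calls$variant)
  expect_equal(b$calls$distance, a$calls$distance)
})

test_that("empty record lists warn and return empty calls", {
  rec <- data.frame(label = integer(), centroid_x = numeric(),
                    centroid_y = numeric(), area_px = integer(),
                    flag = character(), row = integer(), col = integer(),
                    I_a = numeric(), I_b = numeric())
  expect_warning(calls <- call_plate(rec, reference_spectra()), "no eligible")
  expect_equal(nrow(calls$hits), 0)
})

test_that("the pick map marks hits at their block, row and column", {
  fx <- render_spiked_fixture(seed = 64)
  lay <- assign_blocks(fx$layout, 6, 6)
  q <- quantify_plate(fx$rendered, layout = lay)
  calls <- call_plate(q$records, reference_spectra(), lay,
                      majority = "x5_FLuc")
  path <- withr::local_tempfile(fileext = ".txt")
  out <- write_pick_map(calls, lay, path)
  lines <- readLines(path)
  expect_length(lines, lay$n_rows + 1)
  for (i in seq_len(nrow(calls$hits))) {
    h <- calls$hits[i, ]
    expect_equal(substr(lines[h$row + 2], h$col + 1, h$col + 1), "X")
    expect_equal(h$block, block_id(lay, h$row, h$col))
  }
  hits_csv <- utils::read.csv(out[["hits"]])
  expect_equal(nrow(hits_csv), nrow(calls$hits))
})
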