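# Synthetic matrix-deposition plates: ground truth sampling and per-filter
# image rendering. Everything downstream (segmentation, gridding, spectral
# calling) is validated against these simulations, since no deposited
# image data exists for this platform.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# log-normal parameterised by arithmetic mean and CV
rlnorm_mean_cv <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

#' Density-dependent colony radius
#'
#' Colony area shrinks as matrix density grows (nutrient competition at
#' close spacing). The default law is a power decay
#' `r = r_ref * (d_ref / d)^alpha`, monotone non-increasing in density,
#' anchored so `r(d_ref) = r_ref`; `alpha = 0` gives a constant radius.
#'
#' @param density_per_cm2 Matrix density (> 0), colonies per cm^2.
#' @param r_ref_px Reference radius in pixels at density `d_ref`.
#' @param d_ref Reference density (colonies per cm^2).
#' @param alpha Decay exponent (default 1/3).
#' @return Radius in pixels.
#' @export
colony_radius_model <- function(density_per_cm2, r_ref_px = 6, d_ref = 44,
                                alpha = 1/3) {
  if (any(density_per_cm2 <= 0)) stop("density must be positive")
  r_ref_px * (d_ref / density_per_cm2)^alpha
}

#' Sample a ground-truth plate
#'
#' Simulates the outcome of printing one cell per lattice position: each
#' position is independently empty with probability `1 - viability`
#' (deposition viability, default 94%); an occupied position is a doublet
#' (two coincident cells) with probability `doublet_rate`, otherwise a
#' single. Cell variants are drawn from `variant_mix`; each deposited cell
#' gets its own log-normal brightness (total emitted signal, arbitrary
#' units, default mean 0.14 / SD 0.03 matching the clonal-plate intensity
#' calibration). Doublets are co-located: they grow as one colony whose
#' emission is the brightness-weighted sum of the member spectra.
#'
#' @param layout A [plate_layout()].
#' @param viability Colony-forming probability per position, in [0, 1].
#' @param doublet_rate Probability an occupied position holds two cells.
#' @param variant_mix Named fractions summing to 1 (tolerance 1e-9), e.g.
#'   `c(x5_FLuc = 0.995, x5_FLuc_red = 0.005)` for a 0.5% spike-in.
#' @param brightness_mean,brightness_cv Log-normal brightness calibration
#'   (arithmetic mean and coefficient of variation).
#' @param pos_jitter_um Gaussian deposition-placement jitter SD per axis in
#'   micrometres (default 25).
#' @param r_ref_px,d_ref,alpha Passed to [colony_radius_model()]; the plate
#'   density used is occupied count over the fencepost span.
#' @param seed Integer; the plate is fully reproducible from it.
#' @return A `ground_truth_plate`: list with `layout`, `positions`
#'   (data.frame: row, col, occupancy, variant1, variant2, b1, b2,
#'   brightness, radius_px, dx_um, dy_um), `seed` and the parameters.
#' @export
sample_ground_truth <- function(layout, viability = 0.94,
                                doublet_rate = 0.004,
                                variant_mix = c(x5_FLuc = 1),
                                brightness_mean = 0.14,
                                brightness_cv = 0.03 / 0.14,
                                pos_jitter_um = 25,
                                r_ref_px = 6, d_ref = 44, alpha = 1/3,
                                seed = 1) {
  stopifnot(viability >= 0, viability <= 1,
            doublet_rate >= 0, doublet_rate <= 1,
            !is.null(names(variant_mix)), all(variant_mix >= 0))
  if (abs(sum(variant_mix) - 1) > 1e-9)
    stop("variant_mix fractions must sum to 1")
  n <- n_positions(layout)
  grid <- expand.grid(col = 0:(layout$n_cols - 1), row = 0:(layout$n_rows - 1))
  with_seed(seed, {
    occupied <- stats::runif(n) < viability
    dbl <- occupied & (stats::runif(n) < doublet_rate)
    vn <- names(variant_mix)
    v1 <- ifelse(occupied, sample(vn, n, replace = TRUE, prob = variant_mix), NA)
    v2 <- ifelse(dbl, sample(vn, n, replace = TRUE, prob = variant_mix), NA)
    b1 <- ifelse(occupied, rlnorm_mean_cv(n, brightness_mean, brightness_cv), 0)
    b2 <- ifelse(dbl, rlnorm_mean_cv(n, brightness_mean, brightness_cv), 0)
    dx <- stats::rnorm(n, 0, pos_jitter_um)
    dy <- stats::rnorm(n, 0, pos_jitter_um)
  })
  sp <- pmax(layout_span_mm(layout), layout$pitch_um / 1000)  # single-row guard
  dens <- colony_density(sum(occupied), sp[1], sp[2], round_report = FALSE)
  r_px <- colony_radius_model(max(dens, 1), r_ref_px, d_ref, alpha)
  positions <- data.frame(
    row = grid$row, col = grid$col,
    occupancy = ifelse(!occupied, "empty", ifelse(dbl, "double", "single")),
    variant1 = v1, variant2 = v2, b1 = b1, b2 = b2,
    brightness = b1 + b2,
    radius_px = ifelse(occupied, r_px, NA_real_),
    dx_um = ifelse(occupied, dx, 0), dy_um = ifelse(occupied, dy, 0),
    stringsAsFactors = FALSE)
  structure(list(layout = layout, positions = positions, seed = seed,
                 params = list(viability = viability,
                               doublet_rate = doublet_rate,
                               variant_mix = variant_mix,
                               brightness_mean = brightness_mean,
                               brightness_cv = brightness_cv,
                               pos_jitter_um = pos_jitter_um)),
            class = "ground_truth_plate")
}

#' @export
print.ground_truth_plate <- function(x, ...) {
  occ <- x$positions$occupancy
  cat(sprintf("ground_truth_plate: %d positions, %d occupied (%d doublets), seed %d\n",
              length(occ), sum(occ != "empty"), sum(occ == "double"), x$seed))
  invisible(x)
}

#' Ground-truth occupancy table
#'
#' @param gt A [sample_ground_truth()] plate.
#' @return Data.frame `row, col, occupancy, variant, brightness, radius_px`
#'   (doublet variants joined with `+`), occupied positions only.
#' @export
truth_table <- function(gt) {
  p <- gt$positions[gt$positions$occupancy != "empty", ]
  data.frame(row = p$row, col = p$col, occupancy = p$occupancy,
             variant = ifelse(is.na(p$variant2), p$variant1,
                              paste(p$variant1, p$variant2, sep = "+")),
             brightness = p$brightness, radius_px = p$radius_px,
             stringsAsFactors = FALSE)
}

#' Camera and optics model for plate rendering
#'
#' Phenomenological imager model: pixel scale, Gaussian point-spread
#' function, flat dark-background level (charcoal agar is nearly black),
#' Poisson shot noise at `photons_per_unit` photons per intensity unit, and
#' additive Gaussian read noise. Intensities live in [0, 1] (full scale);
#' values past full scale clip and the clip count is reported.
#'
#' @param pixel_um Micrometres per pixel (default 50).
#' @param psf_sigma_px PSF sigma in pixels (0 disables blur).
#' @param background_level Flat background in intensity units.
#' @param read_noise_sd Read noise SD in intensity units.
#' @param shot_noise Logical, apply Poisson shot noise.
#' @param photons_per_unit Conversion gain for shot noise.
#' @param bit_depth 8 or 16, used when images are written to disk.
#' @return An `optics_model` object.
#' @export
optics_model <- function(pixel_um = 50, psf_sigma_px = 1,
                         background_level = 0.01, read_noise_sd = 1e-4,
                         shot_noise = TRUE, photons_per_unit = 1e6,
                         bit_depth = 16) {
  stopifnot(pixel_um > 0, psf_sigma_px >= 0, background_level >= 0,
            read_noise_sd >= 0, photons_per_unit > 0,
            bit_depth %in% c(8, 16))
  structure(list(pixel_um = pixel_um, psf_sigma_px = psf_sigma_px,
                 background_level = background_level,
                 read_noise_sd = read_noise_sd, shot_noise = shot_noise,
                 photons_per_unit = photons_per_unit, bit_depth = bit_depth),
            class = "optics_model")
}

#' Noise-free optics, for oracle-style checks
#' @param ... Overrides passed to [optics_model()].
#' @return An [optics_model()] with blur and all noise disabled.
#' @export
noise_free_optics <- function(...) {
  args <- utils::modifyList(list(psf_sigma_px = 0, background_level = 0,
                                 read_noise_sd = 0, shot_noise = FALSE),
                            list(...))
  do.call(optics_model, args)
}

# disc pixel offsets for a rasterised colony of radius r (px)
disc_offsets <- function(r_px) {
  r <- max(1L, ceiling(r_px))
  d <- expand.grid(dy = -r:r, dx = -r:r)
  d[d$dx^2 + d$dy^2 <= r_px^2, , drop = FALSE]
}

#' Render a plate through a filter set
#'
#' Produces one greyscale image per bandpass filter. Each occupied position
#' contributes a uniform disc of its radius; the disc's summed signal in a
#' band is `b1 * f(variant1, band) + b2 * f(variant2, band)` with `f` the
#' [band_intensity()] fraction, so pre-noise, pre-blur total signal is
#' conserved exactly. The stack is then blurred by the PSF, offset by the
#' background and degraded by shot and read noise.
#'
#' @param gt A [sample_ground_truth()] plate.
#' @param filter_set Named list of [filter_band()]s.
#' @param optics An [optics_model()].
#' @param seed Integer seed for the noise draws.
#' @param variants Named list of [emission_spectrum()]s covering every
#'   variant in the ground truth.
#' @param margin_um Blank margin around the lattice (default one pitch).
#' @return A `rendered_plate`: list with `images` (named list of numeric
#'   matrices indexed `[y, x]`), `truth` (the [truth_table()]), `geometry`
#'   (`pixel_um`, `origin_px` — x,y pixel of lattice node (0,0)),
#'   `band_fractions` (variant x band matrix), `n_clipped`, plus the inputs.
#' @export
render_plate <- function(gt, filter_set = default_filter_set(),
                         optics = optics_model(), seed = gt$seed + 1,
                         variants = default_variants(),
                         margin_um = gt$layout$pitch_um) {
  if (length(filter_set) < 1) stop("need at least one filter band")
  layout <- gt$layout
  pos <- gt$positions[gt$positions$occupancy != "empty", , drop = FALSE]
  used <- unique(c(pos$variant1, stats::na.omit(pos$variant2)))
  if (!all(used %in% names(variants)))
    stop("missing emission model for variant(s): ",
         paste(setdiff(used, names(variants)), collapse = ", "))
  px <- optics$pixel_um
  width  <- ceiling(((layout$n_cols - 1) * layout$pitch_um + 2 * margin_um) / px) + 1L
  height <- ceiling(((layout$n_rows - 1) * layout$pitch_um + 2 * margin_um) / px) + 1L
  origin_px <- c(x = margin_um / px, y = margin_um / px)
  r_px <- if (nrow(pos)) max(pos$radius_px) else 1
  if (2 * r_px + 2 > min(width, height) || margin_um / px < r_px)
    stop("image too small to contain layout at this pixel scale")

  # variant x band fraction matrix
  fr <- t(vapply(variants[used], band_fractions, numeric(length(filter_set)),
                 filter_set = filter_set))
  if (is.null(dim(fr))) fr <- matrix(fr, nrow = length(used))
  rownames(fr) <- used; colnames(fr) <- names(filter_set)

  # colony centres in pixels (jitter included)
  cx <- origin_px["x"] + (pos$col * layout$pitch_um + pos$dx_um) / px
  cy <- origin_px["y"] + (pos$row * layout$pitch_um + pos$dy_um) / px
  off <- disc_offsets(if (nrow(pos)) pos$radius_px[1] else 1)
  n_disc <- nrow(off)
  # linear pixel indices of every colony's disc (no overlap at valid pitch)
  iy <- pmin(pmax(outer(off$dy, round(cy), `+`), 1L), height)
  ix <- pmin(pmax(outer(off$dx, round(cx), `+`), 1L), width)
  lin <- (as.integer(ix) - 1L) * height + as.integer(iy)

  band_signal <- function(b) {  # per-colony total signal in band b
    f2 <- fr[, b][match(pos$variant2, rownames(fr))]  # NA for singles
    pos$b1 * fr[pos$variant1, b] + ifelse(is.na(f2), 0, pos$b2 * f2)
  }

  n_clipped <- 0L
  images <- with_seed(seed, {
    lapply(seq_along(filter_set), function(b) {
      m <- matrix(0, height, width)
      if (nrow(pos)) {
        vals <- rep(band_signal(b) / n_disc, each = n_disc)
        m[lin] <- m[lin] + vals
      }
      if (optics$psf_sigma_px > 0)
        m <- as.matrix(EBImage::gblur(m, sigma = optics$psf_sigma_px))
      m <- m + optics$background_level
      if (optics$shot_noise) {
        g <- optics$photons_per_unit
        m <- matrix(stats::rpois(length(m), pmax(m, 0) * g) / g, height, width)
      }
      if (optics$read_noise_sd > 0)
        m <- m + stats::rnorm(length(m), 0, optics$read_noise_sd)
      clipped <- sum(m > 1)
      n_clipped <<- n_clipped + clipped
      pmin(pmax(m, 0), 1)
    })
  })
  names(images) <- names(filter_set)
  structure(list(images = images, truth = truth_table(gt),
                 geometry = list(pixel_um = px, origin_px = origin_px),
                 band_fractions = fr, n_clipped = n_clipped,
                 filter_set = filter_set, optics = optics,
                 layout = layout, seed = seed),
            class = "rendered_plate")
}

#' @export
print.rendered_plate <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("rendered_plate: %d band(s) %s, %d x %d px, %d colonies, %d clipped px\n",
              length(x$images), paste(names(x$images), collapse = ", "),
              d[1], d[2], nrow(x$truth), x$n_clipped))
  invisible(x)
}

#' Write / read a rendered image stack
#'
#' One file per filter band, the band label as filename suffix
#' (`<prefix>_550-600.tif`). TIFF images are written at the optics model's
#' bit depth; PNG at 8 bits.
#'
#' @param rendered A [render_plate()] result.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix (default `"plate"`).
#' @param format `"tiff"` or `"png"`.
#' @return `write_plate_images` returns the written paths invisibly;
#'   `read_plate_images` returns a named list of numeric matrices keyed by
#'   band label.
#' @export
write_plate_images <- function(rendered, dir, prefix = "plate",
                               format = c("tiff", "png")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "tiff") "tif" else "png"
  paths <- vapply(names(rendered$images), function(b) {
    p <- file.path(dir, sprintf("%s_%s.%s", prefix, b, ext))
    m <- rendered$images[[b]]
    if (format == "tiff") {
      tiff::writeTIFF(m, p, bits.per.sample = rendered$optics$bit_depth)
    } else {
      png::writePNG(m, p)
    }
    p
  }, character(1))
  invisible(paths)
}

#' @rdname write_plate_images
#' @export
read_plate_images <- function(dir, prefix = "plate") {
  files <- list.files(dir, pattern = paste0("^", prefix, "_\\d+-\\d+\\.(tif|tiff|png)$"),
                      full.names = TRUE)
  if (!length(files)) stop("no band images matching '", prefix, "_<low>-<high>' in ", dir)
  bands <- sub("^.*_(\\d+-\\d+)\\.[a-z]+$", "\\1", files)
  imgs <- lapply(files, function(f) {
    m <- if (grepl("\\.png$", f)) png::readPNG(f) else tiff::readTIFF(f)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m
  })
  names(imgs) <- bands
  imgs[order(as.numeric(sub("-.*", "", bands)))]
}

#' Write a ground-truth table as CSV
#' @param gt A [sample_ground_truth()] plate (or a [truth_table()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(gt, path) {
  tt <- if (inherits(gt, "ground_truth_plate")) truth_table(gt) else gt
  utils::write.csv(tt, path, row.names = FALSE)
  invisible(path)
}
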