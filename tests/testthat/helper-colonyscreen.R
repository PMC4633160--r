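# Shared fixtures: everything is built in code at test time.

# paint a uniform disc onto a matrix (centre in px, matrix indexed [y, x])
draw_disc <- function(m, cy, cx, r, total = 1) {
  d <- expand.grid(dy = -ceiling(r):ceiling(r), dx = -ceiling(r):ceiling(r))
  d <- d[d$dx^2 + d$dy^2 <= r^2, ]
  iy <- cy + d$dy; ix <- cx + d$dx
  ok <- iy >= 1 & iy <= nrow(m) & ix >= 1 & ix <= ncol(m)
  m[cbind(iy[ok], ix[ok])] <- m[cbind(iy[ok], ix[ok])] + total / sum(ok)
  m
}

# closed-form Gaussian band fraction (independent of the trapezoid path)
pnorm_band_fraction <- function(peak, fwhm, low, high) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  (stats::pnorm(high, peak, s) - stats::pnorm(low, peak, s)) /
    (stats::pnorm(800, peak, s) - stats::pnorm(400, peak, s))
}

# small spiked plate rendered noise-free: deterministic oracle for the
# quantify -> screen round trip
render_spiked_fixture <- function(seed = 42, n_rows = 12, n_cols = 18,
                                  spike = 0.05, optics = noise_free_optics()) {
  lay <- plate_layout(n_rows, n_cols)
  gt <- sample_ground_truth(
    lay, viability = 0.94, doublet_rate = 0,
    variant_mix = c(x5_FLuc = 1 - spike, x5_FLuc_red = spike),
    pos_jitter_um = 0, seed = seed)
  list(layout = lay, gt = gt, rendered = render_plate(gt, optics = optics))
}
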