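# Two-colour coincidence analysis: a 1:1 eGFP/mCherry mixed print makes
# double depositions visible as double-positive colonies; same-colour
# coincidences are invisible and are corrected for analytically.

#' Classify colonies by two-channel intensity
#'
#' Threshold rule: a colony is a `double` iff both channels exceed their
#' thresholds, a `green-single`/`red-single` if exactly one does, and
#' `below-threshold` otherwise. Default thresholds are Otsu over each
#' channel's colony intensities.
#'
#' @param records Colony records carrying exactly two intensity columns
#'   (see [intensity_matrix()]), or a data.frame with columns `I_green`
#'   and `I_red`.
#' @param thresholds Named numeric length-2 `(green, red)`; NULL for Otsu.
#' @param channels Which intensity columns are (green, red); default the
#'   two `I_` columns in order.
#' @return A `channel_calls` data.frame: `row`, `col` (if present),
#'   `I_green`, `I_red`, `call`.
#' @export
classify_channels <- function(records, thresholds = NULL, channels = NULL) {
  im <- intensity_matrix(records)
  if (is.null(channels)) channels <- colnames(im)
  if (length(channels) != 2 || !all(channels %in% colnames(im)))
    stop("need exactly two intensity channels; got: ",
         paste(colnames(im), collapse = ", "))
  g <- im[, channels[1]]; r <- im[, channels[2]]
  if (is.null(thresholds))
    thresholds <- c(green = otsu_threshold(g), red = otsu_threshold(r))
  gp <- g > thresholds[1]; rp <- r > thresholds[2]
  call <- ifelse(gp & rp, "double",
                 ifelse(gp, "green-single",
                        ifelse(rp, "red-single", "below-threshold")))
  out <- data.frame(I_green = g, I_red = r, call = call,
                    stringsAsFactors = FALSE)
  for (k in c("col", "row")) if (k %in% names(records)) out <- cbind(records[k], out)
  attr(out, "thresholds") <- thresholds
  class(out) <- c("channel_calls", "data.frame")
  out
}

#' Singlet-purity statistics from two-channel calls
#'
#' Singlet purity is the percentage of scoreable colonies that are not
#' double-positive. Only opposite-colour doublets are observable: under a
#' mixing fraction `f`, a random pair is two-coloured with probability
#' `2 f (1 - f)`, so the total doublet rate is estimated as the observed
#' two-colour rate divided by that factor (0.5 at a 1:1 mix, i.e. an
#' observed 0.2% two-colour rate implies 0.4% total). Below-threshold
#' colonies are excluded from the denominator and reported separately.
#' The 95% CI is exact binomial (Clopper-Pearson).
#'
#' @param calls A [classify_channels()] data.frame.
#' @param mix_fraction Fraction of one colour in the input mix, in (0, 1);
#'   default 0.5.
#' @return A `purity_stats` list: `n_colonies`, `n_double`, `n_below`,
#'   `singlet_pct`, `ci95` (on the singlet percentage),
#'   `observed_doublet_pct`, `est_total_doublet_pct`.
#' @export
purity_stats <- function(calls, mix_fraction = 0.5) {
  stopifnot(mix_fraction > 0, mix_fraction < 1)
  n_below <- sum(calls$call == "below-threshold")
  n <- nrow(calls) - n_below
  if (n <= 0) stop("no scoreable colonies")
  n_double <- sum(calls$call == "double")
  obs_pct <- 100 * n_double / n
  ci_d <- stats::binom.test(n_double, n)$conf.int
  structure(list(n_colonies = n, n_double = n_double, n_below = n_below,
                 singlet_pct = 100 - obs_pct,
                 ci95 = 100 - rev(100 * ci_d),
                 observed_doublet_pct = obs_pct,
                 est_total_doublet_pct =
                   obs_pct / (2 * mix_fraction * (1 - mix_fraction))),
            class = "purity_stats")
}

#' @export
print.purity_stats <- function(x, ...) {
  cat(sprintf(
    "purity_stats: %d colonies, %d double-positive -> singlet %.2f%% [%.2f, %.2f]\n",
    x$n_colonies, x$n_double, x$singlet_pct, x$ci95[1], x$ci95[2]))
  cat(sprintf("  observed two-colour doublets %.3f%%, estimated total %.3f%%\n",
              x$observed_doublet_pct, x$est_total_doublet_pct))
  invisible(x)
}

#' Two-channel records straight from a ground-truth plate
#'
#' Builds per-colony channel intensities from a simulated two-variant
#' plate without rendering images: each occupied position's green (red)
#' intensity is the summed brightness of its members of that variant,
#' plus optional Gaussian measurement noise. Useful for large singlet-
#' purity simulations where the imaging stage is not under test.
#'
#' @param gt A [sample_ground_truth()] plate whose variant mix has exactly
#'   two variants.
#' @param channels Character length-2 naming the (green, red) variants;
#'   default the two mix names in order.
#' @param noise_sd Additive Gaussian noise SD on each intensity.
#' @param seed Seed for the noise draws.
#' @return A data.frame with `row`, `col`, `I_green`, `I_red`.
#' @export
channel_records_from_truth <- function(gt, channels = NULL, noise_sd = 0,
                                       seed = gt$seed + 1) {
  mix <- gt$params$variant_mix
  if (is.null(channels)) channels <- names(mix)
  stopifnot(length(channels) == 2)
  p <- gt$positions[gt$positions$occupancy != "empty", , drop = FALSE]
  member_sum <- function(variant) {
    ifelse(p$variant1 == variant, p$b1, 0) +
      ifelse(!is.na(p$variant2) & p$variant2 == variant, p$b2, 0)
  }
  g <- member_sum(channels[1]); r <- member_sum(channels[2])
  if (noise_sd > 0) {
    with_seed(seed, {
      g <- g + stats::rnorm(length(g), 0, noise_sd)
      r <- r + stats::rnorm(length(r), 0, noise_sd)
    })
  }
  data.frame(row = p$row, col = p$col, I_green = g, I_red = r)
}
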