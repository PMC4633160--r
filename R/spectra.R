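#' Emission spectrum model
#'
#' Unimodal emission model for a bioluminescent reporter, parameterised by
#' peak wavelength and full width at half maximum. Firefly luciferase
#' emission is a broad single peak, so a Gaussian in wavelength (unit area
#' over the 400-800 nm support) is used; the shape only enters the pipeline
#' through band integrals, so the exact profile is not critical.
#'
#' @param peak_nm Peak emission wavelength (nm).
#' @param fwhm_nm Full width at half maximum (nm, > 0); default 70.
#' @return An `emission_spectrum` object.
#' @examples
#' emission_spectrum(550)   # stabilised firefly luciferase, x5_FLuc
#' emission_spectrum(615)   # red-shifted S284T variant, x5_FLuc_red
#' @export
emission_spectrum <- function(peak_nm, fwhm_nm = 70) {
  stopifnot(is.numeric(peak_nm), length(peak_nm) == 1, fwhm_nm > 0)
  structure(list(peak_nm = peak_nm, fwhm_nm = fwhm_nm, shape = "gaussian"),
            class = "emission_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("emission_spectrum: gaussian peak %.0f nm, FWHM %.0f nm\n",
              x$peak_nm, x$fwhm_nm))
  invisible(x)
}

# spectral density on the 400-800 nm support, normalised to unit area there
spectrum_density <- function(spectrum, nm) {
  sigma <- spectrum$fwhm_nm / (2 * sqrt(2 * log(2)))
  d <- stats::dnorm(nm, spectrum$peak_nm, sigma)
  norm <- stats::pnorm(800, spectrum$peak_nm, sigma) -
    stats::pnorm(400, spectrum$peak_nm, sigma)
  ifelse(nm < 400 | nm > 800, 0, d / norm)
}

#' Optical bandpass filter
#'
#' @param low_nm,high_nm Transmission window edges in nm; `low < high`,
#'   within the 400-800 nm support.
#' @return A `filter_band` object.
#' @export
filter_band <- function(low_nm, high_nm) {
  stopifnot(low_nm < high_nm, low_nm >= 400, high_nm <= 800)
  structure(list(low_nm = low_nm, high_nm = high_nm), class = "filter_band")
}

#' Default six-filter set
#'
#' Six 50 nm-wide bandpass filters spanning 510-750 nm:
#' 510-560, 550-600, 590-640, 630-680, 670-720, 700-750. The set covers the
#' emission maxima of both the ~550 nm luciferase and its ~615 nm
#' red-shifted variant; the 550-600 and 590-640 windows are the pair used
#' for the red/green band ratio.
#'
#' @return A named list of [filter_band()]s; names like `"550-600"` are the
#'   band labels used in image filenames and intensity tables.
#' @export
default_filter_set <- function() {
  lows <- c(510, 550, 590, 630, 670, 700)
  bands <- lapply(lows, function(l) filter_band(l, l + 50))
  names(bands) <- vapply(bands, band_label, character(1))
  bands
}

#' @rdname default_filter_set
#' @param band A [filter_band()].
#' @export
band_label <- function(band) sprintf("%d-%d", band$low_nm, band$high_nm)

#' Fraction of emission transmitted by a bandpass filter
#'
#' Trapezoidal integral of the unit-normalised emission density over the
#' filter window, on a grid no coarser than 0.5 nm. A band entirely outside
#' the spectrum support returns ~0 rather than erroring.
#'
#' @param spectrum An [emission_spectrum()].
#' @param band A [filter_band()].
#' @return Fraction in [0, 1].
#' @export
band_intensity <- function(spectrum, band) {
  nm <- seq(band$low_nm, band$high_nm,
            length.out = max(3L, ceiling((band$high_nm - band$low_nm) / 0.5) + 1L))
  y <- spectrum_density(spectrum, nm)
  h <- diff(nm)
  sum((y[-1] + y[-length(y)]) / 2 * h)
}

#' Band-fraction vector of a spectrum over a filter set
#'
#' @param spectrum An [emission_spectrum()].
#' @param filter_set List of [filter_band()]s, e.g. [default_filter_set()].
#' @return Named numeric vector of band fractions.
#' @export
band_fractions <- function(spectrum, filter_set = default_filter_set()) {
  vapply(filter_set, function(b) band_intensity(spectrum, b), numeric(1))
}

#' Default variant emission models
#'
#' `x5_FLuc` is the thermostabilised firefly luciferase (peak ~550 nm);
#' `x5_FLuc_red` carries the S284T red shift (peak ~615 nm). Both use the
#' default 70 nm FWHM.
#'
#' @return Named list of [emission_spectrum()]s.
#' @export
default_variants <- function() {
  list(x5_FLuc = emission_spectrum(550), x5_FLuc_red = emission_spectrum(615))
}
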