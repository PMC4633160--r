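# Per-colony multi-point emission spectra and rare-variant calling.
# Each colony's six band intensities are scaled to a unit maximum and
# matched against model reference spectra; colonies whose nearest
# reference is a non-majority variant are hits, reported on a pick map.

#' Normalise a band-intensity vector to unit maximum
#'
#' Division by the maximum entry makes the peak position the dominant
#' feature of the spectrum and removes per-colony brightness. Small
#' negative entries (background-subtraction noise) are clamped to zero
#' first.
#'
#' @param intensities Numeric vector with at least one positive entry.
#' @return Vector in [0, 1] with maximum exactly 1.
#' @export
normalize_spectrum <- function(intensities) {
  x <- pmax(intensities, 0)
  m <- max(x)
  if (!is.finite(m) || m <= 0) stop("no signal: all band intensities are zero")
  x / m
}

#' Reference spectra for a variant panel
#'
#' Band-fraction vectors of each variant's emission model through the
#' filter set, normalised like colony spectra. References come from the
#' emission model, not from data, so calling is deterministic.
#'
#' @param variants Named list of [emission_spectrum()]s.
#' @param filter_set Named list of [filter_band()]s.
#' @return Matrix, one row per variant, columns = band labels.
#' @export
reference_spectra <- function(variants = default_variants(),
                              filter_set = default_filter_set()) {
  m <- t(vapply(variants, function(v)
    normalize_spectrum(band_fractions(v, filter_set)),
    numeric(length(filter_set))))
  rownames(m) <- names(variants); colnames(m) <- names(filter_set)
  m
}

#' Classify one normalised spectrum
#'
#' Nearest reference by Euclidean distance. The call is `confident` when
#' the best distance is at most `max_distance` and the runner-up distance
#' exceeds it by at least `margin` (relative); ambiguous spectra — e.g. a
#' mixed doublet midway between two variants — fail the margin rule.
#' `red_ratio` is the intensity ratio of the two `ratio_bands` (default
#' 590-640 over 550-600), unaffected by the unit-maximum scaling.
#'
#' @param norm Normalised spectrum (see [normalize_spectrum()]).
#' @param references Matrix from [reference_spectra()] (>= 2 variants).
#' @param max_distance Maximum distance for a confident call (default 0.6).
#' @param margin Required relative runner-up margin (default 0.2).
#' @param ratio_bands Indices of the (green, red) ratio bands, default
#'   `c(2, 3)` of the six-band set.
#' @return List: `variant`, `distance`, `red_ratio`, `confident`.
#' @export
classify_spectrum <- function(norm, references, max_distance = 0.6,
                              margin = 0.2, ratio_bands = c(2, 3)) {
  if (length(norm) != ncol(references))
    stop("spectrum length does not match reference band count")
  d <- sqrt(rowSums(sweep(references, 2, norm)^2))
  o <- order(d)
  best <- d[o[1]]; runner <- d[o[2]]
  list(variant = rownames(references)[o[1]],
       distance = unname(best),
       red_ratio = unname(norm[ratio_bands[2]] / norm[ratio_bands[1]]),
       confident = best <= max_distance && runner >= (1 + margin) * best &&
         (best > 0 || runner > 0))
}

#' Call spectral variants for every colony on a plate
#'
#' Normalises each eligible colony's band intensities, classifies against
#' the references, and reports hits: colonies confidently called as any
#' non-majority variant. Flagged colonies (merged components, node
#' conflicts, off-grid) are excluded from calling.
#'
#' @param records Grid-assigned [measure_colonies()] records (from
#'   [assign_to_grid()] or [quantify_plate()]).
#' @param references [reference_spectra()] matrix.
#' @param layout The [plate_layout()] (for block ids on the pick map).
#' @param majority Majority variant name; default the most frequent call.
#' @param max_distance,margin,ratio_bands Passed to [classify_spectrum()].
#' @return A `spectral_calls` list: `calls` (data.frame row, col, block,
#'   s1..s6, variant, distance, red_ratio, confident), `hits` (subset of
#'   confident non-majority calls), `majority`, `n_excluded`.
#' @export
call_plate <- function(records, references = reference_spectra(),
                       layout = NULL, majority = NULL,
                       max_distance = 0.6, margin = 0.2,
                       ratio_bands = c(2, 3)) {
  eligible <- records$flag == "" & !is.na(records$row)
  n_excluded <- sum(!eligible)
  rec <- records[eligible, , drop = FALSE]
  if (nrow(rec) == 0) {
    warning("no eligible colonies to call")
    empty <- data.frame()
    return(structure(list(calls = empty, hits = empty, majority = NA,
                          n_excluded = n_excluded), class = "spectral_calls"))
  }
  im <- intensity_matrix(rec)
  norm <- t(apply(im, 1, normalize_spectrum))
  # vectorised nearest-reference distances
  d2 <- sapply(rownames(references), function(v)
    rowSums(sweep(norm, 2, references[v, ])^2))
  d2 <- matrix(d2, nrow = nrow(norm),
               dimnames = list(NULL, rownames(references)))
  d <- sqrt(d2)
  bi <- max.col(-d, ties.method = "first")
  best <- d[cbind(seq_len(nrow(d)), bi)]
  runner <- apply(d, 1, function(x) sort(x)[2])
  confident <- best <= max_distance & runner >= (1 + margin) * best &
    (best > 0 | runner > 0)
  variant <- rownames(references)[bi]
  if (is.null(majority))
    majority <- names(sort(table(variant), decreasing = TRUE))[1]
  sm <- as.data.frame(norm)
  names(sm) <- paste0("s", seq_len(ncol(norm)))
  calls <- data.frame(row = rec$row, col = rec$col,
                      block = if (!is.null(layout)) block_id(layout, rec$row, rec$col) else 0L,
                      sm,
                      variant = variant, distance = best,
                      red_ratio = norm[, ratio_bands[2]] / norm[, ratio_bands[1]],
                      confident = confident,
                      stringsAsFactors = FALSE)
  hits <- calls[calls$confident & calls$variant != majority, , drop = FALSE]
  structure(list(calls = calls, hits = hits, majority = majority,
                 n_excluded = n_excluded),
            class = "spectral_calls")
}

#' @export
print.spectral_calls <- function(x, ...) {
  cat(sprintf("spectral_calls: %d colonies called (majority %s), %d hit(s), %d excluded\n",
              nrow(x$calls), x$majority, nrow(x$hits), x$n_excluded))
  invisible(x)
}

#' Write a pick map for hit retrieval
#'
#' Emits a machine-readable hit CSV (`block,row,col,variant`) and a
#' human-readable plate map: one character per lattice node — `.` not
#' called, `o` majority, `X` hit — so a hit can be located at the bench by
#' block, row and column.
#'
#' @param calls A [call_plate()] result.
#' @param layout The printed [plate_layout()].
#' @param path Path of the text map; the hit CSV goes to the same name with
#'   extension `.csv`.
#' @return Invisibly, the two paths written.
#' @export
write_pick_map <- function(calls, layout, path) {
  map <- matrix(".", layout$n_rows, layout$n_cols)
  if (nrow(calls$calls)) {
    map[cbind(calls$calls$row + 1, calls$calls$col + 1)] <- "o"
  }
  if (nrow(calls$hits)) {
    map[cbind(calls$hits$row + 1, calls$hits$col + 1)] <- "X"
  }
  lines <- c(sprintf("# pick map: %d x %d, majority %s, %d hit(s)",
                     layout$n_rows, layout$n_cols, calls$majority,
                     nrow(calls$hits)),
             apply(map, 1, paste, collapse = ""))
  writeLines(lines, path)
  csv <- paste0(tools::file_path_sans_ext(path), ".csv")
  hits <- calls$hits[, c("block", "row", "col", "variant"), drop = FALSE]
  utils::write.csv(hits, csv, row.names = FALSE)
  invisible(c(map = path, hits = csv))
}

#' Write spectral calls as CSV
#' @param calls A [call_plate()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_csv <- function(calls, path) {
  utils::write.csv(calls$calls, path, row.names = FALSE)
  invisible(path)
}
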