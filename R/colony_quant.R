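# Colony detection and quantification on matrix plates: threshold +
# connected components (EBImage), background-subtracted per-band
# photometry, and lattice assignment via a fitted similarity transform.

#' Otsu threshold of a numeric vector or matrix
#'
#' Computed on the value range of the data itself (a relative threshold),
#' so segmentation is invariant to global linear intensity rescaling.
#'
#' @param x Numeric vector or matrix.
#' @param levels Number of grey levels for the histogram (default 512).
#' @return Threshold on the original intensity scale.
#' @export
otsu_threshold <- function(x, levels = 512L) {
  r <- range(x, finite = TRUE)
  if (r[1] == r[2]) return(r[2])  # flat image: nothing above threshold
  m <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  EBImage::otsu(m, range = r, levels = levels)
}

#' Segment colonies in a plate image
#'
#' Thresholds the image and labels connected components; components
#' smaller than `min_area_px` are dropped. The default threshold is Otsu
#' computed on square-root intensities above the image minimum
#' (variance-stabilising for shot-noise-limited images, and less swayed by
#' the wide brightness spread across colonies than a linear-domain Otsu),
#' then mapped back to the intensity scale; it depends only on relative
#' intensities. Components whose area exceeds
#' `merge_area_factor` times the median component area are flagged as
#' probable merged neighbours — two colonies deposited closer than their
#' diameters fuse into one component and cannot be attributed to a single
#' lattice node, mirroring the treatment of coincident depositions.
#'
#' @param image 2-D numeric matrix (typically the max-projection across
#'   bands, see [max_projection()]).
#' @param min_area_px Minimum component area in pixels (default 4).
#' @param threshold_method `"otsu"` or a fixed numeric threshold.
#' @param merge_area_factor Area-outlier factor for the merge flag
#'   (default 1.7).
#' @return List: `labels` (integer matrix, 0 = background), `n` components,
#'   `merged` (integer vector of flagged labels), `threshold`.
#' @export
segment_colonies <- function(image, min_area_px = 4,
                             threshold_method = "otsu",
                             merge_area_factor = 1.7) {
  if (!is.matrix(image)) stop("image must be a 2-D matrix")
  thr <- if (identical(threshold_method, "otsu")) {
    lo <- min(image)
    lo + otsu_threshold(sqrt(pmax(image - lo, 0)))^2
  } else if (is.numeric(threshold_method)) {
    threshold_method
  } else stop("unknown threshold_method")
  mask <- image > thr
  labels <- EBImage::bwlabel(mask)
  labels <- as.matrix(labels)
  if (max(labels) > 0) {
    areas <- tabulate(labels[labels > 0])
    keep <- which(areas >= min_area_px)
    relab <- integer(length(areas))
    relab[keep] <- seq_along(keep)
    labels[labels > 0] <- relab[labels[labels > 0]]
    areas <- areas[keep]
  } else areas <- integer(0)
  merged <- if (length(areas) > 2) {
    which(areas > merge_area_factor * stats::median(areas))
  } else integer(0)
  list(labels = labels, n = length(areas), merged = as.integer(merged),
       threshold = thr)
}

#' Max-projection of an image stack
#' @param images Named list of same-size matrices (one per band).
#' @return Matrix of per-pixel maxima.
#' @export
max_projection <- function(images) {
  Reduce(pmax, images)
}

#' Measure colonies across a band stack
#'
#' Per colony and band, the integrated intensity is the sum of pixel values
#' inside the component minus `area * background`, with the background
#' estimated either from a local annulus (non-foreground pixels in the
#' component's bounding box expanded by `annulus_px`; robust to plate-level
#' illumination gradients) or as the global median of unlabelled pixels.
#'
#' @param seg A [segment_colonies()] result (or a label matrix).
#' @param images Named list of band images, dims matching the label map.
#' @param background `"local-median"` (default) or `"global"`.
#' @param annulus_px Annulus width in pixels (default 3).
#' @return A `colony_records` data.frame: `label, centroid_x, centroid_y,
#'   area_px, flag`, one `I_<band>` column per band (background-subtracted
#'   integrated intensity) and `row`/`col` (NA until [assign_to_grid()]).
#' @export
measure_colonies <- function(seg, images,
                             background = c("local-median", "global"),
                             annulus_px = 3) {
  background <- match.arg(background)
  labels <- if (is.list(seg)) seg$labels else seg
  merged <- if (is.list(seg)) seg$merged else integer(0)
  if (!all(vapply(images, function(m) identical(dim(m), dim(labels)), logical(1))))
    stop("label map dimensions must match every band image")
  nlab <- max(labels)
  h <- nrow(labels)
  fg <- labels > 0
  idx <- which(fg)
  lab <- labels[idx]
  ys <- (idx - 1L) %% h + 1L
  xs <- (idx - 1L) %/% h + 1L
  area <- tabulate(lab, nbins = nlab)
  cx <- rowsum(xs, lab)[, 1] / area
  cy <- rowsum(ys, lab)[, 1] / area

  intens <- matrix(0, nlab, length(images),
                   dimnames = list(NULL, names(images)))
  if (background == "global") {
    for (b in seq_along(images)) {
      v <- images[[b]]
      bg <- stats::median(v[!fg])
      intens[, b] <- rowsum(v[idx], lab)[, 1] - area * bg
    }
  } else {
    by_lab <- split(seq_along(idx), lab)
    w <- ncol(labels)
    for (k in seq_len(nlab)) {
      sel <- by_lab[[as.character(k)]]
      y0 <- max(1L, min(ys[sel]) - annulus_px); y1 <- min(h, max(ys[sel]) + annulus_px)
      x0 <- max(1L, min(xs[sel]) - annulus_px); x1 <- min(w, max(xs[sel]) + annulus_px)
      win_bg <- !fg[y0:y1, x0:x1, drop = FALSE]
      for (b in seq_along(images)) {
        win <- images[[b]][y0:y1, x0:x1, drop = FALSE]
        bg <- stats::median(win[win_bg])
        intens[k, b] <- sum(images[[b]][idx[sel]]) - area[k] * bg
      }
    }
  }
  rec <- data.frame(label = seq_len(nlab), centroid_x = cx, centroid_y = cy,
                    area_px = area,
                    flag = ifelse(seq_len(nlab) %in% merged, "merged", ""),
                    row = NA_integer_, col = NA_integer_,
                    stringsAsFactors = FALSE)
  icols <- as.data.frame(intens)
  names(icols) <- paste0("I_", colnames(intens))
  rec <- cbind(rec, icols)
  class(rec) <- c("colony_records", "data.frame")
  rec
}

#' Band-intensity matrix of colony records
#' @param records A [measure_colonies()] data.frame.
#' @return Numeric matrix, one column per band (names without the `I_`
#'   prefix).
#' @export
intensity_matrix <- function(records) {
  cols <- grep("^I_", names(records), value = TRUE)
  m <- as.matrix(records[cols])
  dimnames(m) <- list(NULL, sub("^I_", "", cols))
  m
}

#' Assign detected colonies to lattice nodes
#'
#' Fits a similarity transform (translation + scale, optional small
#' rotation) from lattice coordinates to detected centroids by iterated
#' nearest-node least squares, then snaps each colony to its nearest node.
#' Colonies farther than `pitch/2` from any node stay unassigned
#' (`off-grid`); when two colonies claim one node the nearer keeps it and
#' the other is flagged `conflict`. Errors if the median fit residual
#' exceeds `pitch/4`.
#'
#' @param records A [measure_colonies()] data.frame (>= 4 colonies).
#' @param layout The [plate_layout()] that was printed.
#' @param pixel_um Image scale, micrometres per pixel.
#' @param max_iter Fit iterations (default 10).
#' @return List: `records` with `row`/`col` filled and flags updated,
#'   `unoccupied` (data.frame of empty nodes), `transform` (list with
#'   `scale`, `rotation_rad`, `origin_px`, `median_resid_um`).
#' @export
assign_to_grid <- function(records, layout, pixel_um, max_iter = 10) {
  ok <- records$flag != "merged"
  if (sum(ok) < 4) stop("need at least 4 unflagged colonies to fit the grid")
  z <- complex(real = records$centroid_x * pixel_um,
               imaginary = records$centroid_y * pixel_um)
  pitch <- layout$pitch_um
  # init: unit scale, translation matching the lattice bounding box
  b <- complex(real = 1, imaginary = 0)
  a <- complex(real = min(Re(z[ok])), imaginary = min(Im(z[ok])))
  node <- NULL
  for (it in seq_len(max_iter)) {
    w_est <- (z - a) / b
    col <- pmin(pmax(round(Re(w_est) / pitch), 0), layout$n_cols - 1)
    row <- pmin(pmax(round(Im(w_est) / pitch), 0), layout$n_rows - 1)
    node_new <- complex(real = col * pitch, imaginary = row * pitch)
    if (!is.null(node) && all(node_new[ok] == node[ok])) break
    node <- node_new
    # least-squares similarity on currently assigned pairs
    zf <- z[ok]; wf <- node[ok]
    wc <- wf - mean(wf); zc <- zf - mean(zf)
    b <- sum(Conj(wc) * zc) / sum(Mod(wc)^2)
    a <- mean(zf) - b * mean(wf)
  }
  resid <- Mod(z - (a + b * node))
  if (stats::median(resid[ok]) > pitch / 4)
    stop("grid fit failed: median residual ", round(stats::median(resid[ok]), 1),
         " um exceeds pitch/4")
  col <- Re(node) / pitch
  row <- Im(node) / pitch
  assign_ok <- ok & resid <= pitch / 2
  records$flag[ok & !assign_ok] <- "off-grid"
  # conflicts: one node claimed by several colonies -> nearest wins
  key <- ifelse(assign_ok, row * layout$n_cols + col, NA)
  ord <- order(key, resid)
  dup <- duplicated(key[ord], incomparables = NA)
  loser <- ord[dup]
  records$flag[loser] <- "conflict"
  assign_ok[loser] <- FALSE
  records$row[assign_ok] <- as.integer(row[assign_ok])
  records$col[assign_ok] <- as.integer(col[assign_ok])
  taken <- unique(stats::na.omit(key[assign_ok]))
  all_keys <- 0:(n_positions(layout) - 1)
  empty <- setdiff(all_keys, taken)
  unoccupied <- data.frame(row = empty %/% layout$n_cols,
                           col = empty %% layout$n_cols)
  list(records = records,
       unoccupied = unoccupied,
       transform = list(scale = Mod(b), rotation_rad = Arg(b),
                        origin_px = c(x = Re(a) / pixel_um, y = Im(a) / pixel_um),
                        median_resid_um = stats::median(resid[ok])))
}

#' Quantify a rendered or on-disk plate end to end
#'
#' Convenience wrapper: max-projection, [segment_colonies()],
#' [measure_colonies()], [assign_to_grid()].
#'
#' @param images Named list of band images, or a [render_plate()] result.
#' @param layout The printed [plate_layout()] (taken from a rendered plate
#'   if not given).
#' @param pixel_um Image scale (taken from a rendered plate if not given).
#' @param min_area_px,threshold_method,background Passed through.
#' @return As [assign_to_grid()], plus `segmentation` and a `qc` list
#'   (colony count, viability estimate, flag counts, fit residual).
#' @export
quantify_plate <- function(images, layout = NULL, pixel_um = NULL,
                           min_area_px = 4, threshold_method = "otsu",
                           background = "local-median") {
  if (inherits(images, "rendered_plate")) {
    if (is.null(layout)) layout <- images$layout
    if (is.null(pixel_um)) pixel_um <- images$geometry$pixel_um
    images <- images$images
  }
  stopifnot(!is.null(layout), !is.null(pixel_um))
  seg <- segment_colonies(max_projection(images), min_area_px = min_area_px,
                          threshold_method = threshold_method)
  rec <- measure_colonies(seg, images, background = background)
  asg <- assign_to_grid(rec, layout, pixel_um)
  qc <- list(n_detected = nrow(rec),
             n_assigned = sum(!is.na(asg$records$row)),
             n_unoccupied = nrow(asg$unoccupied),
             viability_estimate = 1 - nrow(asg$unoccupied) / n_positions(layout),
             flags = table(asg$records$flag[asg$records$flag != ""]),
             median_resid_um = asg$transform$median_resid_um,
             threshold = seg$threshold)
  c(asg, list(segmentation = seg, qc = qc))
}

#' Write colony records as CSV
#' @param records A [measure_colonies()] data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_colonies_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_colonies_csv
#' @export
read_colonies_csv <- function(path) {
  rec <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  rec$flag[is.na(rec$flag)] <- ""
  class(rec) <- c("colony_records", "data.frame")
  rec
}
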