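#' Deposition matrix layout
#'
#' A `plate_layout` describes the lattice onto which a flow sorter deposits
#' single cells: `n_rows` x `n_cols` positions at a fixed centre-to-centre
#' pitch. Coordinates are 0-based `(row, col)`, row-major, origin at the
#' top-left position; y increases downward to match raster image indexing.
#' Physical units are micrometres.
#'
#' @param n_rows,n_cols Positive integers, lattice shape.
#' @param pitch_um Centre-to-centre spacing in micrometres (default 500).
#' @param origin_um Numeric length-2, physical `(x, y)` of position
#'   `(row 0, col 0)` in micrometres.
#' @param block_rows,block_cols Optional sub-format block shape; see
#'   [assign_blocks()].
#' @return An object of class `plate_layout`.
#' @seealso [make_layout()] to derive the shape from a point count and an
#'   aspect ratio, [position_coords()], [assign_blocks()].
#' @export
plate_layout <- function(n_rows, n_cols, pitch_um = 500,
                         origin_um = c(0, 0),
                         block_rows = NULL, block_cols = NULL) {
  stopifnot(length(n_rows) == 1, length(n_cols) == 1,
            n_rows >= 1, n_cols >= 1,
            n_rows == as.integer(n_rows), n_cols == as.integer(n_cols),
            is.numeric(pitch_um), pitch_um > 0,
            length(origin_um) == 2)
  if (!is.null(block_rows) || !is.null(block_cols)) {
    stopifnot(!is.null(block_rows), !is.null(block_cols),
              block_rows >= 1, block_cols >= 1)
  }
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pitch_um = as.numeric(pitch_um),
                 origin_um = as.numeric(origin_um),
                 block_rows = if (is.null(block_rows)) NULL else as.integer(block_rows),
                 block_cols = if (is.null(block_cols)) NULL else as.integer(block_cols)),
            class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("plate_layout: %d x %d (%d positions), pitch %.0f um\n",
              x$n_rows, x$n_cols, n_positions(x), x$pitch_um))
  sp <- layout_span_mm(x)
  cat(sprintf("  span %.1f x %.1f mm (fencepost)\n", sp[1], sp[2]))
  if (!is.null(x$block_rows))
    cat(sprintf("  blocks: %d x %d positions\n", x$block_rows, x$block_cols))
  invisible(x)
}

#' Number of positions in a layout
#' @param layout A [plate_layout()].
#' @return Integer, `n_rows * n_cols`.
#' @export
n_positions <- function(layout) layout$n_rows * layout$n_cols

#' Physical span of a layout
#'
#' Fencepost extent of the lattice: `(n_cols - 1) * pitch` wide by
#' `(n_rows - 1) * pitch` high.
#'
#' @param layout A [plate_layout()].
#' @return Numeric length-2 `(width_mm, height_mm)`.
#' @export
layout_span_mm <- function(layout) {
  c(width_mm  = (layout$n_cols - 1) * layout$pitch_um / 1000,
    height_mm = (layout$n_rows - 1) * layout$pitch_um / 1000)
}

#' Choose the lattice shape for a point count and target aspect ratio
#'
#' Deposition matrices are printed with a rows:columns ratio near 1:1.5 so
#' the print fills the footprint of standard micro-well plates. Given a
#' total point count, this picks the integer factorisation
#' `n_rows * n_cols = n_points` whose column/row ratio is closest to
#' `aspect_ratio`, ties broken toward more columns. The canonical formats
#' (384 = 16x24, 3750 = 50x75, 25350 = 130x195) all factor exactly at 1.5.
#'
#' @param n_points Total number of lattice positions (>= 1).
#' @param aspect_ratio Target `n_cols / n_rows` (default 1.5).
#' @param pitch_um,origin_um Passed to [plate_layout()].
#' @return A [plate_layout()].
#' @details If no factor pair comes within a factor of 4 of the requested
#'   ratio (e.g. a large prime count), the function errors and names the
#'   nearest achievable factorisations. Layouts that deliberately break the
#'   aspect rule (such as a 50x81 multiplexer plate) should be built
#'   directly with [plate_layout()].
#' @examples
#' make_layout(384, 1.5)    # 16 x 24
#' make_layout(3750, 1.5)   # 50 x 75
#' @export
make_layout <- function(n_points, aspect_ratio = 1.5, pitch_um = 500,
                        origin_um = c(0, 0)) {
  stopifnot(n_points >= 1, n_points == as.integer(n_points), aspect_ratio > 0)
  n_points <- as.integer(n_points)
  divs <- which(n_points %% seq_len(n_points) == 0)   # all row counts
  rows <- divs
  cols <- n_points %/% rows
  ratio <- cols / rows
  err <- abs(ratio - aspect_ratio)
  best <- which(err == min(err))
  if (length(best) > 1) best <- best[which.max(cols[best])]  # more columns
  # ratio-of-ratios mismatch guard: prime counts with extreme aspect mismatch
  mis <- max(ratio[best] / aspect_ratio, aspect_ratio / ratio[best])
  if (mis > 4) {
    ord <- order(err)[seq_len(min(2L, length(err)))]
    stop(sprintf(
      "no factorisation of %d comes near aspect %.3g; nearest: %s",
      n_points, aspect_ratio,
      paste(sprintf("%dx%d (ratio %.3g)", rows[ord], cols[ord], ratio[ord]),
            collapse = ", ")))
  }
  plate_layout(rows[best], cols[best], pitch_um = pitch_um,
               origin_um = origin_um)
}

#' Physical coordinates of lattice positions
#'
#' @param layout A [plate_layout()].
#' @param row,col 0-based position indices (vectorised, recycled).
#' @return A data.frame with columns `row`, `col`, `x_um`, `y_um`.
#' @export
position_coords <- function(layout, row, col) {
  n <- max(length(row), length(col))
  row <- rep_len(as.integer(row), n); col <- rep_len(as.integer(col), n)
  if (any(row < 0 | row >= layout$n_rows | col < 0 | col >= layout$n_cols))
    stop("position out of layout bounds")
  data.frame(row = row, col = col,
             x_um = layout$origin_um[1] + col * layout$pitch_um,
             y_um = layout$origin_um[2] + row * layout$pitch_um)
}

#' Sub-format a layout into blocks
#'
#' High-density plates are sub-formatted into blocks so hit colonies can be
#' located and picked easily; a hit is reported as (block, row, col).
#' Block ids are row-major over the block grid,
#' `id = (row %/% block_rows) * ceil(n_cols / block_cols) + (col %/% block_cols)`;
#' edge blocks may be ragged.
#'
#' @param layout A [plate_layout()].
#' @param block_rows,block_cols Block shape in positions (>= 1).
#' @return The layout with block shape recorded.
#' @export
assign_blocks <- function(layout, block_rows, block_cols) {
  stopifnot(block_rows >= 1, block_cols >= 1)
  layout$block_rows <- as.integer(block_rows)
  layout$block_cols <- as.integer(block_cols)
  layout
}

#' Block id of lattice positions
#'
#' @param layout A [plate_layout()] with blocks assigned (otherwise all 0).
#' @param row,col 0-based indices (vectorised).
#' @return Integer vector of block ids.
#' @export
block_id <- function(layout, row, col) {
  if (is.null(layout$block_rows)) return(rep_len(0L, max(length(row), length(col))))
  bpr <- ceiling(layout$n_cols / layout$block_cols)  # blocks per block-row
  as.integer((as.integer(row) %/% layout$block_rows) * bpr +
               (as.integer(col) %/% layout$block_cols))
}

#' Colony density of a printed area
#'
#' @param n_colonies Number of colonies (>= 0).
#' @param width_mm,height_mm Printed area extent in millimetres (> 0).
#' @param round_report Round to the nearest integer, matching the "~394
#'   colonies/cm2" reporting style (default TRUE).
#' @return Colonies per square centimetre.
#' @export
colony_density <- function(n_colonies, width_mm, height_mm,
                           round_report = TRUE) {
  stopifnot(n_colonies >= 0)
  if (width_mm <= 0 || height_mm <= 0) stop("plate area must be positive")
  d <- n_colonies / (width_mm * height_mm / 100)
  if (round_report) round(d) else d
}

#' Expected colony count at a given deposition viability
#'
#' Deposited single cells grow into colonies with an average viability of
#' about 94%, so a 3,750-point matrix yields about 3,525 colonies.
#'
#' @param n_positions Number of deposition positions.
#' @param viability Probability a deposited cell forms a colony, in [0, 1].
#' @return Rounded expected colony count.
#' @export
expected_colonies <- function(n_positions, viability) {
  stopifnot(n_positions >= 1)
  if (viability < 0 || viability > 1) stop("viability must be in [0, 1]")
  round(n_positions * viability)
}

#' Read / write a layout as YAML or JSON
#'
#' The on-disk form is a flat mapping
#' `{n_rows, n_cols, pitch_um, origin_um, block_rows, block_cols}`;
#' the format follows the file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param layout A [plate_layout()].
#' @param path File path.
#' @return `write_layout` returns `path` invisibly; `read_layout` returns a
#'   [plate_layout()].
#' @export
write_layout <- function(layout, path) {
  x <- layout[c("n_rows", "n_cols", "pitch_um", "origin_um",
                "block_rows", "block_cols")]
  x <- x[!vapply(x, is.null, logical(1))]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  plate_layout(x$n_rows, x$n_cols,
               pitch_um = if (is.null(x$pitch_um)) 500 else x$pitch_um,
               origin_um = if (is.null(x$origin_um)) c(0, 0) else unlist(x$origin_um),
               block_rows = x$block_rows, block_cols = x$block_cols)
}
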