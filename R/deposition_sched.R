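# Deposition scheduling and throughput for conventional single-stream
# printing versus the sort-stream multiplexer. The rate limit is the
# electromechanical dead time while the plate handler translates between
# stops; a multiplexer deposits a burst of n_streams adjacent positions
# per stop, cutting the stop count per row by that factor.

#' Build a deposition schedule
#'
#' Rows are visited in serpentine order with one y-translation per row;
#' within a row the handler stops `ceil(n_cols / n_streams)` times and the
#' sorter writes a burst of up to `n_streams` adjacent positions at each
#' stop. With one stream this is the conventional one-stop-per-position
#' schedule.
#'
#' @param layout A [plate_layout()].
#' @param n_streams Burst size of the multiplexer (1 = conventional).
#' @return A `sort_schedule`: `layout`, `n_streams`, `stops_per_row`
#'   (= x-translations per row), `x_translations_per_row`,
#'   `y_translations`, `total_stops`, `burst_size`.
#' @export
schedule <- function(layout, n_streams = 1) {
  stopifnot(n_streams >= 1, n_streams == as.integer(n_streams))
  if (n_streams > layout$n_cols)
    stop("n_streams exceeds the number of columns")
  spr <- as.integer(ceiling(layout$n_cols / n_streams))
  structure(list(layout = layout, n_streams = as.integer(n_streams),
                 stops_per_row = spr, x_translations_per_row = spr,
                 y_translations = layout$n_rows,
                 total_stops = layout$n_rows * spr,
                 burst_size = as.integer(n_streams)),
            class = "sort_schedule")
}

#' @export
print.sort_schedule <- function(x, ...) {
  cat(sprintf(
    "sort_schedule: %d x %d plate, %d stream(s): %d stops/row, %d rows, %d total stops\n",
    x$layout$n_rows, x$layout$n_cols, x$n_streams, x$stops_per_row,
    x$y_translations, x$total_stops))
  invisible(x)
}

#' Serpentine stop sequence of a schedule
#'
#' @param sched A [schedule()].
#' @return Data.frame, one line per stop in execution order: `row`,
#'   `stop`, `first_col`, `n_deposited` (burst size clipped at the row
#'   end). Summing `n_deposited` recovers the full point count whatever
#'   the stream count.
#' @export
schedule_stops <- function(sched) {
  lay <- sched$layout
  rows <- 0:(lay$n_rows - 1)
  out <- do.call(rbind, lapply(rows, function(r) {
    first <- seq(0, lay$n_cols - 1, by = sched$n_streams)
    if (r %% 2 == 1) first <- rev(first)  # serpentine
    data.frame(row = r, stop = seq_along(first) - 1L, first_col = first,
               n_deposited = pmin(sched$n_streams, lay$n_cols - first))
  }))
  rownames(out) <- NULL
  out
}

#' Throughput model
#'
#' @param t_stop_s Electromechanical dead time per stop, seconds (>= 0).
#' @param t_drop_s Per-particle deposition time within a burst (default 0:
#'   burst deposition runs at the sort rate, negligible against the dead
#'   time).
#' @return A `throughput_model` object.
#' @export
throughput_model <- function(t_stop_s, t_drop_s = 0) {
  stopifnot(t_stop_s >= 0, t_drop_s >= 0)
  structure(list(t_stop_s = t_stop_s, t_drop_s = t_drop_s),
            class = "throughput_model")
}

#' Predicted time to print a plate
#'
#' `total_stops * t_stop + n_particles * t_drop`.
#'
#' @param sched A [schedule()].
#' @param model A [throughput_model()].
#' @param n_particles Particles deposited (default the full layout).
#' @return Seconds.
#' @export
plate_time <- function(sched, model, n_particles = n_positions(sched$layout)) {
  if (n_particles > n_positions(sched$layout))
    stop("more particles than layout positions")
  sched$total_stops * model$t_stop_s + n_particles * model$t_drop_s
}

#' Calibrate the per-stop dead time from a measured plate time
#'
#' @param t_measured_s Measured wall time for the plate, seconds.
#' @param sched The [schedule()] the measurement was taken under.
#' @return `t_stop_s = t_measured_s / total_stops` (assumes `t_drop = 0`).
#' @export
calibrate_t_stop <- function(t_measured_s, sched) {
  stopifnot(t_measured_s > 0)
  t_measured_s / sched$total_stops
}

#' Throughput improvement between two plate times
#'
#' @param t_baseline_s,t_new_s Seconds; baseline must be positive.
#' @return Percent reduction, `100 * (t_baseline - t_new) / t_baseline`,
#'   reported to one decimal.
#' @export
percent_improvement <- function(t_baseline_s, t_new_s) {
  if (t_baseline_s <= 0) stop("baseline time must be positive")
  round(100 * (t_baseline_s - t_new_s) / t_baseline_s, 1)
}

#' Deposition rate
#'
#' @param n_particles Particles deposited (>= 0).
#' @param t_seconds Elapsed time (> 0).
#' @param round_report Round to the nearest integer for reporting.
#' @return Particles per second.
#' @export
deposition_rate <- function(n_particles, t_seconds, round_report = FALSE) {
  if (t_seconds <= 0) stop("time must be positive")
  r <- n_particles / t_seconds
  if (round_report) round(r) else r
}

#' Charge-attenuation levels for a multiplexed burst
#'
#' The multiplexer attenuates successive sort charge pulses so successive
#' droplets deflect through smaller angles and land at adjacent positions
#' while the plate stays still. Under a linear charge-to-deflection model
#' the i-th of `n_streams` pulses is attenuated to
#' `(full_deflection - i * stream_pitch) / full_deflection`, a strictly
#' decreasing ladder from 1.
#'
#' @param n_streams Number of streams in a burst.
#' @param stream_pitch_um Landing-position spacing (= lattice pitch).
#' @param full_deflection_um Landing offset of the unattenuated pulse.
#' @return Numeric vector of factors in (0, 1], length `n_streams`.
#' @export
attenuation_levels <- function(n_streams, stream_pitch_um,
                               full_deflection_um) {
  stopifnot(n_streams >= 1, stream_pitch_um > 0, full_deflection_um > 0)
  if (n_streams * stream_pitch_um > full_deflection_um + stream_pitch_um)
    stop("geometry infeasible: streams span more than the full deflection")
  i <- 0:(n_streams - 1)
  f <- (full_deflection_um - i * stream_pitch_um) / full_deflection_um
  if (any(f <= 0)) stop("geometry infeasible: non-positive attenuation factor")
  f
}
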