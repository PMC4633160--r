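# End-to-end plumbing: a serialisable run configuration and a staged
# pipeline (simulate -> quantify -> screen, plus coincidence and
# scheduling) whose outputs are fully reproducible from (config, seed).

#' Default run configuration
#'
#' A plain named list, YAML round-trippable, covering every stage. Any
#' subset can be overridden via `...` (named top-level sections are
#' replaced element-wise).
#'
#' @param seed Integer master seed recorded in all outputs.
#' @param output_dir Directory for stage outputs.
#' @param ... Section overrides, e.g.
#'   `layout = list(n_points = 384, aspect_ratio = 1.5)`.
#' @return A `run_config` list.
#' @export
default_run_config <- function(seed = 1, output_dir = "colonyscreen_out", ...) {
  cfg <- list(
    seed = as.integer(seed),
    output_dir = output_dir,
    image_format = "tiff",
    layout = list(n_points = 3750, aspect_ratio = 1.5, pitch_um = 500,
                  block_rows = 25, block_cols = 25),
    simulation = list(viability = 0.94, doublet_rate = 0.004,
                      variant_mix = list(x5_FLuc = 0.995, x5_FLuc_red = 0.005),
                      brightness_mean = 0.14, brightness_cv = 0.03 / 0.14,
                      pos_jitter_um = 25),
    variants = list(x5_FLuc = list(peak_nm = 550, fwhm_nm = 70),
                    x5_FLuc_red = list(peak_nm = 615, fwhm_nm = 70)),
    filters = lapply(c(510, 550, 590, 630, 670, 700),
                     function(l) list(low_nm = l, high_nm = l + 50)),
    optics = list(pixel_um = 50, psf_sigma_px = 1, background_level = 0.01,
                  read_noise_sd = 1e-4, shot_noise = TRUE,
                  photons_per_unit = 1e6, bit_depth = 16),
    segmentation = list(min_area_px = 4, threshold_method = "otsu",
                        background = "local-median"),
    classification = list(max_distance = 0.6, margin = 0.2,
                          majority = "x5_FLuc"),
    schedule = list(n_streams = 9, t_measured_s = 1563)
  )
  structure(merge_config(cfg, list(...)), class = c("run_config", "list"))
}

# two-level merge: named keys inside a section are replaced wholesale
# (no recursive merging — a new variant_mix replaces the default one)
merge_config <- function(base, override) {
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]]) &&
                     !is.null(names(override[[k]]))) {
      sec <- base[[k]]
      for (kk in names(override[[k]])) sec[[kk]] <- override[[k]][[kk]]
      sec
    } else override[[k]]
  }
  base
}

#' Load / save a run configuration (YAML)
#' @param path YAML file path.
#' @return `load_run_config` returns a `run_config`; `save_run_config`
#'   returns `path` invisibly.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  required <- c("seed", "output_dir", "layout", "simulation", "optics")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("invalid config, missing key(s): ", paste(missing, collapse = ", "))
  structure(merge_config(unclass(default_run_config()), cfg),
            class = c("run_config", "list"))
}

#' @rdname load_run_config
#' @param config A `run_config`.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

cfg_layout <- function(config) {
  lc <- config$layout
  lay <- if (!is.null(lc$n_rows)) {
    plate_layout(lc$n_rows, lc$n_cols,
                 pitch_um = if (is.null(lc$pitch_um)) 500 else lc$pitch_um)
  } else {
    make_layout(lc$n_points,
                aspect_ratio = if (is.null(lc$aspect_ratio)) 1.5 else lc$aspect_ratio,
                pitch_um = if (is.null(lc$pitch_um)) 500 else lc$pitch_um)
  }
  if (!is.null(lc$block_rows)) lay <- assign_blocks(lay, lc$block_rows, lc$block_cols)
  lay
}

cfg_variants <- function(config) {
  lapply(config$variants, function(v)
    emission_spectrum(v$peak_nm, if (is.null(v$fwhm_nm)) 70 else v$fwhm_nm))
}

cfg_filters <- function(config) {
  bands <- lapply(config$filters, function(b) filter_band(b$low_nm, b$high_nm))
  names(bands) <- vapply(bands, band_label, character(1))
  bands
}

cfg_optics <- function(config) do.call(optics_model, config$optics)

#' Run pipeline stages
#'
#' Stages and their outputs (all under `config$output_dir`):
#' \describe{
#'   \item{simulate}{band images `plate_<band>.tif`, `truth.csv`,
#'     `layout.yaml`, `config.yaml`}
#'   \item{quantify}{`colonies.csv`, `qc.json` (reads the band images)}
#'   \item{screen}{`calls.csv`, `pickmap.txt`, `pickmap.csv`
#'     (reads `colonies.csv`)}
#'   \item{coincidence}{`purity.json`, `scatter.csv` (two-channel runs)}
#'   \item{schedule}{`schedule.json` (throughput report, conventional vs
#'     multiplexed)}
#'   \item{run-all}{simulate + quantify + screen}
#' }
#' Every output is a deterministic function of (config, seed).
#'
#' @param config A [default_run_config()]-style list.
#' @param mode One of the stages above.
#' @return Invisibly, a list of stage results and output paths.
#' @export
run_pipeline <- function(config = default_run_config(),
                         mode = c("run-all", "simulate", "quantify",
                                  "screen", "coincidence", "schedule")) {
  mode <- match.arg(mode)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  lay <- cfg_layout(config)
  res <- list()

  if (mode %in% c("simulate", "run-all", "coincidence")) {
    sim <- config$simulation
    gt <- sample_ground_truth(
      lay, viability = sim$viability, doublet_rate = sim$doublet_rate,
      variant_mix = unlist(sim$variant_mix),
      brightness_mean = sim$brightness_mean, brightness_cv = sim$brightness_cv,
      pos_jitter_um = sim$pos_jitter_um, seed = config$seed)
    res$ground_truth <- gt
    write_truth_csv(gt, file.path(out, "truth.csv"))
    write_layout(lay, file.path(out, "layout.yaml"))
    save_run_config(config, file.path(out, "config.yaml"))
  }
  if (mode %in% c("simulate", "run-all")) {
    rendered <- render_plate(res$ground_truth, filter_set = cfg_filters(config),
                             optics = cfg_optics(config),
                             variants = cfg_variants(config),
                             seed = config$seed + 1)
    res$rendered <- rendered
    write_plate_images(rendered, out, format = config$image_format)
    message("simulate: ", nrow(rendered$truth), " colonies on ",
            lay$n_rows, "x", lay$n_cols, " -> ", out)
  }
  if (mode %in% c("quantify", "run-all")) {
    images <- if (!is.null(res$rendered)) res$rendered$images else {
      if (!length(list.files(out, pattern = "^plate_")))
        stop("quantify: no band images 'plate_<band>' found in ", out)
      read_plate_images(out)
    }
    seg <- config$segmentation
    q <- quantify_plate(images, layout = lay,
                        pixel_um = config$optics$pixel_um,
                        min_area_px = seg$min_area_px,
                        threshold_method = seg$threshold_method,
                        background = seg$background)
    res$quantified <- q
    write_colonies_csv(q$records, file.path(out, "colonies.csv"))
    qc <- q$qc; qc$flags <- as.list(qc$flags); qc$seed <- config$seed
    jsonlite::write_json(qc, file.path(out, "qc.json"), auto_unbox = TRUE,
                         digits = NA)
    message("quantify: ", qc$n_detected, " colonies, viability estimate ",
            round(qc$viability_estimate, 3))
  }
  if (mode %in% c("screen", "run-all")) {
    records <- if (!is.null(res$quantified)) res$quantified$records else {
      p <- file.path(out, "colonies.csv")
      if (!file.exists(p)) stop("screen: missing ", p)
      read_colonies_csv(p)
    }
    cls <- config$classification
    refs <- reference_spectra(cfg_variants(config), cfg_filters(config))
    calls <- call_plate(records, refs, layout = lay,
                        majority = cls$majority,
                        max_distance = cls$max_distance, margin = cls$margin)
    res$calls <- calls
    write_calls_csv(calls, file.path(out, "calls.csv"))
    write_pick_map(calls, lay, file.path(out, "pickmap.txt"))
    message("screen: ", nrow(calls$hits), " hit(s) of ", nrow(calls$calls),
            " colonies called")
  }
  if (mode == "coincidence") {
    ch <- channel_records_from_truth(res$ground_truth)
    calls <- classify_channels(ch)
    ps <- purity_stats(calls,
                       mix_fraction = unlist(config$simulation$variant_mix)[1])
    res$purity <- ps
    utils::write.csv(as.data.frame(calls), file.path(out, "scatter.csv"),
                     row.names = FALSE)
    jsonlite::write_json(c(unclass(ps), list(seed = config$seed)),
                         file.path(out, "purity.json"), auto_unbox = TRUE,
                         digits = NA)
    message("coincidence: singlet purity ", round(ps$singlet_pct, 2), "%")
  }
  if (mode == "schedule") {
    sc <- config$schedule
    base <- schedule(lay, 1)
    multi <- schedule(lay, sc$n_streams)
    t_stop <- if (!is.null(sc$t_stop_s)) sc$t_stop_s else
      calibrate_t_stop(sc$t_measured_s, base)
    tm <- throughput_model(t_stop)
    t1 <- plate_time(base, tm); tn <- plate_time(multi, tm)
    rep <- list(n_rows = lay$n_rows, n_cols = lay$n_cols,
                n_streams = sc$n_streams, t_stop_s = t_stop,
                stops_conventional = base$total_stops,
                stops_multiplexed = multi$total_stops,
                x_translations_per_row = multi$x_translations_per_row,
                y_translations = multi$y_translations,
                predicted_time_s = tn, conventional_time_s = t1,
                improvement_pct = percent_improvement(t1, tn),
                rate_per_s = deposition_rate(n_positions(lay), tn))
    res$schedule <- rep
    jsonlite::write_json(rep, file.path(out, "schedule.json"),
                         auto_unbox = TRUE, digits = NA)
    message("schedule: ", rep$stops_multiplexed, " stops, ",
            round(rep$predicted_time_s, 1), " s predicted")
  }
  invisible(res)
}
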