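## Orchestration: configuration, staged execution with logging, and a
## static report of the aligned, fingered record.

#' Pipeline configuration
#'
#' All stage parameters with their defaults: camera at 117 fps, touch
#' sensors at 200 Hz, block gap 12.5 ms (2.5 touch sample periods),
#' spurious-touch area fraction 0.2, slide threshold 1 mm, three anchor
#' notes, calibration at camera frame 0.
#'
#' @param ... overrides of the defaults.
#' @return named list of class `keyfusion_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    camera_fps = 117,
    touch_rate_hz = 200,
    gap_max_s = 0.0125,
    area_fraction = 0.2,
    marker_check = FALSE,
    slide_threshold_mm = 1.0,
    min_anchors = 3L,
    calibration_frame = 0L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    kf_validation_error("unknown config keys: %s", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  validate_config(structure(cfg, class = "keyfusion_config"))
}

#' @rdname default_config
#' @param cfg a config list.
#' @export
validate_config <- function(cfg) {
  kf_assert(cfg$camera_fps > 0, "camera_fps must be > 0")
  kf_assert(cfg$touch_rate_hz > 0, "touch_rate_hz must be > 0")
  kf_assert(cfg$gap_max_s > 0, "gap_max_s must be > 0")
  kf_assert(cfg$area_fraction >= 0 && cfg$area_fraction <= 1,
            "area_fraction must be in [0, 1]")
  kf_assert(cfg$slide_threshold_mm >= 0, "slide_threshold_mm must be >= 0")
  kf_assert(cfg$min_anchors >= 1L, "min_anchors must be >= 1")
  kf_assert(cfg$calibration_frame >= 0L, "calibration_frame must be >= 0")
  invisible(cfg)
}

#' @rdname default_config
#' @param path YAML config file; keys override the defaults.
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_config, vals)
}

#' Run the full pipeline on a bundle directory
#'
#' Stages, in order: read, align, annotate-markers, finger, analyze,
#' write. Each stage's parameters and record counts are appended to
#' `pipeline.log` in the output directory; a failing stage aborts with
#' its name while earlier outputs are retained. Identical inputs and
#' configuration produce identical outputs.
#'
#' @param bundle_dir directory with `markers.csv`, `touch.csv`,
#'   `midi.csv`, `polygons.json`, `anchors.csv`.
#' @param config a `keyfusion_config`.
#' @param out_dir output directory (default `<bundle_dir>/out`).
#' @param report also write `report.png` (default TRUE).
#' @return invisibly, list(bundle, analysis, out_dir).
#' @export
run_pipeline <- function(bundle_dir, config = default_config(),
                         out_dir = file.path(bundle_dir, "out"),
                         report = TRUE) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  cat(sprintf("keyfusion pipeline\nconfig: %s\n",
              paste(sprintf("%s=%s", names(config), unlist(config)),
                    collapse = " ")),
      file = log_path)
  logln <- function(...) cat(sprintf(...), "\n", file = log_path, append = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      logln("stage %s FAILED: %s", name, conditionMessage(e))
      kf_stage_error("stage %s failed: %s", name, conditionMessage(e))
    })
  }

  bundle <- stage("read", read_bundle_dir(bundle_dir))
  logln("stage read: %d marker rows, %d touch rows, %d midi events, %d keys",
        nrow(bundle$markers), nrow(bundle$touches), nrow(bundle$midi),
        length(bundle$polygons))

  bundle <- stage("align", align_bundle(bundle, camera_fps = config$camera_fps,
                                        min_anchors = config$min_anchors))
  logln("stage align: fps=%g factor=%.8f offset=%.6f; %d notes",
        config$camera_fps, bundle$alignment$touch_rate_factor,
        bundle$alignment$midi_offset, nrow(bundle$notes))

  mk_ann <- stage("annotate-markers",
                  marker_key_annotation(bundle$markers, bundle$polygons))
  utils::write.csv(mk_ann, file.path(out_dir, "marker_keys.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  logln("stage annotate-markers: %d visible marker rows annotated", nrow(mk_ann))

  bundle <- stage("finger", finger_bundle(bundle, gap_max_s = config$gap_max_s,
                                          area_fraction = config$area_fraction,
                                          marker_check = config$marker_check))
  logln("stage finger: gap=%gs area_frac=%g; %d blocks, %d/%d notes fingered",
        config$gap_max_s, config$area_fraction, nrow(bundle$blocks),
        sum(!is.na(bundle$notes$finger)), nrow(bundle$notes))

  analysis <- stage("analyze",
                    analyze_bundle(bundle,
                                   calibration_frame = config$calibration_frame,
                                   slide_threshold_mm = config$slide_threshold_mm))
  logln("stage analyze: %d ci samples, %d timed notes, %d transition windows",
        nrow(analysis$ci), nrow(analysis$timing),
        length(unique(analysis$transitions$window_id)))

  stage("write", {
    write_annotated(bundle, out_dir, transitions = analysis$transitions)
    for (nm in c("ci", "timing")) {
      df <- analysis[[nm]]
      num <- vapply(df, is.double, logical(1))
      df[num] <- lapply(df[num], function(x) formatC(x, digits = 15, format = "g"))
      utils::write.csv(df, file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE, quote = FALSE, na = "")
    }
  })
  if (report) {
    stage("report", report_plots(analysis, file.path(out_dir, "report.png")))
  }
  logln("pipeline complete")
  invisible(list(bundle = bundle, analysis = analysis, out_dir = out_dir))
}

#' Static summary report
#'
#' Three panels grouped by finger: mean curvature index per phalanx,
#' mean anticipatory/release contact timing, and mean quantity-of-motion
#' index per transition segment.
#'
#' @param analysis result of [analyze_bundle()].
#' @param path output PNG path.
#' @return invisibly, `path`.
#' @export
report_plots <- function(analysis, path) {
  grDevices::png(path, width = 1400, height = 500)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 3), mar = c(6, 4, 3, 1))
  ci <- analysis$ci
  if (nrow(ci)) {
    key <- paste(substr(ci$hand, 1, 1), ci$finger, ci$phalanx, sep = "_")
    m <- tapply(ci$ci, key, mean)
    graphics::barplot(m, las = 2, ylab = "mean CI",
                      main = "Curvature index by finger")
    graphics::abline(h = 1, lty = 2)
  } else {
    graphics::plot.new(); graphics::title("Curvature index (no data)")
  }
  tm <- analysis$timing
  if (nrow(tm)) {
    key <- paste(substr(tm$hand, 1, 1), tm$finger, sep = "_")
    ma <- tapply(tm$anticipatory_s, key, mean)
    mr <- tapply(tm$release_time_s, key, mean)
    ylim <- range(c(ma, mr, 0))
    graphics::plot(seq_along(ma), ma, pch = 19, col = "blue", ylim = ylim,
                   xaxt = "n", xlab = "", ylab = "seconds",
                   main = "Contact timing by finger")
    graphics::points(seq_along(mr), mr, pch = 17, col = "red")
    graphics::axis(1, at = seq_along(ma), labels = names(ma), las = 2)
    graphics::abline(h = 0, lty = 2)
    graphics::legend("topright", c("anticipatory", "release"),
                     pch = c(19, 17), col = c("blue", "red"), bty = "n")
  } else {
    graphics::plot.new(); graphics::title("Contact timing (no data)")
  }
  tr <- analysis$transitions
  if (nrow(tr)) {
    key <- paste(substr(tr$hand, 1, 1), tr$finger, sep = "_")
    m <- tapply(tr$qmi_marker, list(tr$segment, key), mean, na.rm = TRUE)
    graphics::barplot(m, beside = TRUE, las = 2, ylab = "mean QMI",
                      legend.text = rownames(m),
                      main = "Marker QMI by transition segment")
    graphics::abline(h = 1, lty = 2)
  } else {
    graphics::plot.new(); graphics::title("Transitions (no data)")
  }
  invisible(path)
}
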