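#' Build and validate a pipeline run configuration
#'
#' A single configuration object drives the full contactless breathing
#' analysis: simulate (or read) sensor streams, calibrate thermal frames,
#' track the mouth ROI, extract breathing series, and run the spectral /
#' windowed analyses. All module-level parameter objects are validated up
#' front, before any stage runs.
#'
#' @param out_dir Output directory for intermediate CSVs and the report.
#' @param sensors `"thermal"`, `"depth"` or `"both"`.
#' @param scene [scene_params()] to simulate inputs, or `NULL` to read
#'   recorded frames from `thermal_dir` / `depth_dir`.
#' @param thermal_dir,depth_dir Input frame directories when not simulating.
#' @param frame_shape Full thermal frame shape; required (for the bar
#'   layout) when thermal frames are read from disk.
#' @param classifier Path to a saved digit-classifier JSON, or `NULL` to
#'   train the standard bar reader from the built-in renderer.
#' @param track [roi_track_params()].
#' @param f_low,f_high,taps Band-pass design, Hz / coefficient count.
#' @param window_len_s Windowed-feature length, s.
#' @param schedule Optional [activity_schedule()] for delay analysis.
#' @param chest_roi Chest [roi()] for depth extraction; defaults to the
#'   simulated scene's chest ROI.
#' @param fs Sampling frequency when reading frames from disk.
#' @param seed Integer seed controlling every random stage.
#' @return A validated `"run_config"`.
#' @export
run_config <- function(out_dir, sensors = "both", scene = scene_params(),
                       thermal_dir = NULL, depth_dir = NULL,
                       frame_shape = NULL, classifier = NULL,
                       track = roi_track_params(), f_low = 0.05,
                       f_high = 1.5, taps = 512L, window_len_s = 60,
                       schedule = NULL, chest_roi = NULL, fs = NULL,
                       seed = 1L) {
  if (!sensors %in% c("thermal", "depth", "both")) {
    abort("sensors must be 'thermal', 'depth' or 'both'")
  }
  thermal_on <- sensors %in% c("thermal", "both")
  depth_on <- sensors %in% c("depth", "both")
  if (is.null(scene)) {
    if (thermal_on) {
      if (is.null(thermal_dir)) abort("thermal run needs a scene or thermal_dir")
      if (is.null(frame_shape)) {
        abort("calibration bar layout unknown: frame_shape required for recorded thermal frames")
      }
      if (is.null(fs)) abort("fs required for recorded frames")
    }
    if (depth_on) {
      if (is.null(depth_dir)) abort("depth run needs a scene or depth_dir")
      if (is.null(chest_roi)) abort("depth run from disk needs a chest_roi")
      if (is.null(fs)) abort("fs required for recorded frames")
    }
  } else {
    stopifnot(inherits(scene, "scene_params"))
    if (thermal_on && !scene$include_bar) {
      abort("calibration bar layout missing: scene must include the bar for a thermal run")
    }
  }
  stopifnot(inherits(track, "roi_track_params"))
  if (!is.null(schedule)) stopifnot(inherits(schedule, "activity_schedule"))
  structure(
    list(out_dir = out_dir, sensors = sensors, scene = scene,
         thermal_dir = thermal_dir, depth_dir = depth_dir,
         frame_shape = frame_shape, classifier = classifier, track = track,
         f_low = f_low, f_high = f_high, taps = taps,
         window_len_s = window_len_s, schedule = schedule,
         chest_roi = chest_roi, fs = fs, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Train the standard calibration-bar reader
#'
#' Convenience wrapper training the digit network on the bar renderer's
#' full character set (digits, '.', '-', and the blank sign cell) with
#' default jitter.
#'
#' @param n_per_class Training renderings per class.
#' @param seed Seed for data generation and weight initialisation.
#' @param ... Passed to [train_digit_classifier()].
#' @return A `"digit_classifier"`.
#' @export
default_bar_classifier <- function(n_per_class = 200, seed = 1L, ...) {
  ts <- make_digit_training_set(n_per_class, seed = seed,
                                chars = c(bar_charset(), " "))
  train_digit_classifier(ts$glyphs, ts$labels, seed = seed + 1L, ...)
}

#' Global breathing frequency of a record
#'
#' Band-passes the mean-removed series, takes the DFT and picks the largest
#' in-band bin — the whole-record breathing-rate estimate, accurate to
#' `fs / N`.
#'
#' @param signal A [breath_signal()].
#' @param f_low,f_high Analysis band, Hz.
#' @param taps Band-pass length (clipped to the record length).
#' @return One-row tibble: `freq_hz`, `freq_bpm`, `bin`.
#' @export
estimate_breathing_frequency <- function(signal, f_low = 0.05, f_high = 1.5,
                                         taps = 512L) {
  fs <- signal_fs(signal)
  spec <- design_bandpass(f_low, f_high, taps = min(taps, length(signal$value)),
                          fs = fs, verify = FALSE)
  filt <- fir_filter(breath_signal(signal$value - mean(signal$value), fs), spec)
  breathing_frequency(dft_spectrum(filt), f_low, f_high)
}

write_csv_plain <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes calibration, ROI tracking, series extraction and spectral /
#' windowed analysis for the configured sensors, writing every intermediate
#' table as CSV plus a final JSON report. Outputs are identical for
#' identical config and seed.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages?
#' @return The report, invisibly (also written to
#'   `file.path(out_dir, "report.json")`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  thermal_on <- config$sensors %in% c("thermal", "both")
  depth_on <- config$sensors %in% c("depth", "both")
  report <- list(sensors = config$sensors, seed = config$seed)

  if (thermal_on) {
    if (!is.null(config$scene)) {
      say("simulating thermal stream (%d frames)", config$scene$n_frames)
      scene <- simulate_thermal_sequence(config$scene)
      frames <- scene$frames
      layout <- scene$layout
      fs <- config$scene$fs
    } else {
      say("reading thermal frames from %s", config$thermal_dir)
      frames <- read_thermal_frames(config$thermal_dir)
      layout <- bar_layout(config$frame_shape)
      fs <- config$fs
    }
    model <- if (is.null(config$classifier)) {
      say("training calibration-bar reader")
      default_bar_classifier(seed = config$seed)
    } else {
      load_classifier(config$classifier)
    }
    say("calibrating %d frames", length(frames))
    cal <- calibrate_frames(frames, layout, model)
    write_csv_plain(cal$scales, file.path(config$out_dir, "calibration.csv"))
    say("tracking mouth ROI")
    trace <- track_mouth_roi(cal$temps, fs, config$track)
    write_csv_plain(trace, file.path(config$out_dir, "thermal_trace.csv"))
    tser <- extract_thermal_series(cal$temps, trace, fs)
    bf <- estimate_breathing_frequency(tser, config$f_low, config$f_high,
                                       config$taps)
    wf <- windowed_features(tser, config$window_len_s, config$f_low, config$f_high)
    write_csv_plain(wf, file.path(config$out_dir, "thermal_windows.csv"))
    report$thermal <- list(
      n_frames = length(frames),
      fallback_rate = mean(trace$fallback),
      freq_hz = bf$freq_hz, freq_bpm = bf$freq_bpm, bin = bf$bin
    )
    if (!is.null(config$schedule)) {
      report$thermal$delays <- as.list(
        response_delay(wf, config$schedule, value = "freq_bpm")
      )
    }
  }

  if (depth_on) {
    if (!is.null(config$scene)) {
      say("simulating depth stream (%d frames)", config$scene$n_frames)
      dsc <- simulate_depth_sequence(config$scene)
      dframes <- dsc$frames
      croi <- config$chest_roi %||% dsc$truth$chest_roi
      fs <- config$scene$fs
    } else {
      say("reading depth frames from %s", config$depth_dir)
      dframes <- read_depth_frames(config$depth_dir)
      croi <- config$chest_roi
      fs <- config$fs
    }
    dser <- extract_depth_series(dframes, croi, fs)
    write_csv_plain(dser, file.path(config$out_dir, "depth_series.csv"))
    dbf <- estimate_breathing_frequency(dser, config$f_low, config$f_high,
                                        config$taps)
    dwf <- windowed_features(dser, config$window_len_s, config$f_low, config$f_high)
    write_csv_plain(dwf, file.path(config$out_dir, "depth_windows.csv"))
    report$depth <- list(
      n_frames = length(dframes),
      freq_hz = dbf$freq_hz, freq_bpm = dbf$freq_bpm, bin = dbf$bin
    )
  }

  if (thermal_on && depth_on) {
    report$agreement <- list(
      same_bin = report$thermal$bin == report$depth$bin,
      freq_diff_bpm = report$thermal$freq_bpm - report$depth$freq_bpm
    )
  }
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  say("report written to %s", file.path(config$out_dir, "report.json"))
  invisible(report)
}
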