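#' Synthetic scene parameters
#'
#' Describes a paired thermal/depth recording of a breathing subject with
#' known ground truth. The thermal stream shows a smooth warm face on a
#' cooler background with a rectangular mouth patch whose temperature
#' oscillates at the breathing frequency; each frame is rendered to 8-bit
#' grey over its own temperature span and (optionally) carries a calibration
#' bar printing that span. The depth stream shows a chest patch whose
#' distance from the sensor oscillates at the same frequency.
#'
#' @param frame_shape Thermal frame `(rows, cols)` including the bar strip.
#' @param fs Sampling frequency, Hz. Must exceed twice `breath_freq`.
#' @param duration Record length, s; `duration * fs` must be an integer >= 2.
#' @param breath_freq Breathing frequency, Hz, within the 0.05-1.5 Hz
#'   analysis band.
#' @param mouth_size Mouth patch `(rows, cols)` in pixels.
#' @param mouth_center_path `NULL` for a static mouth, a length-2 `(row, col)`
#'   centre, or an `n x 2` per-frame trajectory in image-region coordinates
#'   (0-based, below the bar). See [mouth_path_linear()], [mouth_path_sine()].
#' @param base_temp Mean exhaled-air temperature at the mouth, degC.
#' @param breath_amplitude Amplitude of the mouth-temperature oscillation, degC.
#' @param temp_drift_rate Linear drift of the mouth temperature, degC per
#'   minute.
#' @param noise_std Thermal per-pixel Gaussian noise, degC.
#' @param chest_mean_dist Mean chest distance, m (within the 0.4-4 m sensor
#'   range).
#' @param chest_amplitude Chest motion amplitude, m.
#' @param depth_noise_std Depth per-pixel Gaussian noise, m.
#' @param depth_frame_shape Depth frame `(rows, cols)`.
#' @param chest_roi Fixed chest [roi()] in depth-frame coordinates, or `NULL`
#'   for a centred default.
#' @param include_bar Embed a calibration bar in thermal frames?
#' @param seed Integer seed; sequences are bit-identical for equal seeds.
#' @return A validated `"scene_params"` list.
#' @export
scene_params <- function(frame_shape = c(56L, 80L), fs = 10, duration = 300,
                         breath_freq = 0.25, mouth_size = c(10L, 14L),
                         mouth_center_path = NULL, base_temp = 27,
                         breath_amplitude = 1, temp_drift_rate = 0,
                         noise_std = 0.1, chest_mean_dist = 1.5,
                         chest_amplitude = 0.005, depth_noise_std = 0.003,
                         depth_frame_shape = c(48L, 64L), chest_roi = NULL,
                         include_bar = TRUE, seed = 1L) {
  p <- list(frame_shape = as.integer(frame_shape), fs = fs, duration = duration,
            breath_freq = breath_freq, mouth_size = as.integer(mouth_size),
            mouth_center_path = mouth_center_path, base_temp = base_temp,
            breath_amplitude = breath_amplitude,
            temp_drift_rate = temp_drift_rate, noise_std = noise_std,
            chest_mean_dist = chest_mean_dist, chest_amplitude = chest_amplitude,
            depth_noise_std = depth_noise_std,
            depth_frame_shape = as.integer(depth_frame_shape),
            chest_roi = chest_roi, include_bar = include_bar,
            seed = as.integer(seed))
  n <- p$duration * p$fs
  if (!isTRUE(all.equal(n, round(n))) || round(n) < 2) {
    abort("duration * fs must be an integer number of frames >= 2")
  }
  p$n_frames <- as.integer(round(n))
  if (p$breath_freq < 0.05 || p$breath_freq > 1.5) {
    abort("breath_freq must lie in the 0.05-1.5 Hz analysis band")
  }
  if (p$fs <= 2 * p$breath_freq) abort("fs must exceed twice breath_freq (Nyquist)")
  if (p$noise_std < 0 || p$depth_noise_std < 0) abort("noise_std must be >= 0")
  if (p$chest_mean_dist < 0.4 || p$chest_mean_dist > 4) {
    abort("chest_mean_dist outside the 0.4-4 m sensor range")
  }
  structure(p, class = "scene_params")
}

#' Mouth-centre trajectories
#'
#' Helpers building per-frame `(row, col)` mouth-centre paths in image-region
#' coordinates. `mouth_path_linear` moves at a constant pixel velocity after
#' an optional stationary lead-in; `mouth_path_sine` oscillates about a fixed
#' centre.
#'
#' @param from Length-2 start centre `(row, col)`.
#' @param velocity Length-2 displacement per frame, px.
#' @param n_frames Total frames.
#' @param hold_frames Frames to stay at `from` before moving.
#' @return `n_frames x 2` matrix.
#' @export
mouth_path_linear <- function(from, velocity, n_frames, hold_frames = 0L) {
  steps <- pmax(0, seq_len(n_frames) - 1L - hold_frames)
  cbind(from[1] + steps * velocity[1], from[2] + steps * velocity[2])
}

#' @rdname mouth_path_linear
#' @param center Length-2 mean centre `(row, col)`.
#' @param amplitude Length-2 oscillation amplitude `(rows, cols)`, px.
#' @param period_s Oscillation period, s.
#' @param fs Sampling frequency, Hz.
#' @export
mouth_path_sine <- function(center, amplitude, period_s, fs, n_frames) {
  t <- (seq_len(n_frames) - 1L) / fs
  s <- sin(2 * pi * t / period_s)
  cbind(center[1] + amplitude[1] * s, center[2] + amplitude[2] * s)
}

# smooth static face temperature field for the image region
face_field <- function(shape, background = 22, face_peak = 12) {
  r <- matrix(seq_len(shape[1]) - 1L, shape[1], shape[2])
  c <- matrix(seq_len(shape[2]) - 1L, shape[1], shape[2], byrow = TRUE)
  rc <- 0.35 * shape[1]; cc <- 0.5 * shape[2]
  sr <- shape[1] / 3; sc <- shape[2] / 4
  background + face_peak * exp(-((r - rc)^2 / (2 * sr^2) + (c - cc)^2 / (2 * sc^2)))
}

# integer patch ROI (image-region coordinates) from a fractional centre
patch_roi <- function(center, size) {
  r0 <- round(center[1] - size[1] / 2)
  c0 <- round(center[2] - size[2] / 2)
  roi(r0, c0, r0 + size[1], c0 + size[2])
}

resolve_mouth_path <- function(params, img_shape) {
  n <- params$n_frames
  path <- params$mouth_center_path
  if (is.null(path)) path <- c(0.7 * img_shape[1], 0.5 * img_shape[2])
  if (is.null(dim(path))) path <- matrix(path, n, 2, byrow = TRUE)
  if (nrow(path) != n) abort("mouth_center_path must have one row per frame")
  path
}

#' Simulate a thermal breathing video
#'
#' Renders `duration * fs` 8-bit grey frames: a static smooth face field, a
#' mouth patch at `base_temp + drift + breath_amplitude * sin(2 pi f t)`,
#' i.i.d. Gaussian pixel noise, per-frame grey encoding over the frame's own
#' span rounded outwards to 0.1 degC, and a calibration bar printing that
#' span. Ground truth (mouth ROI, noise-free mouth mean temperature, spans)
#' is returned alongside.
#'
#' @param params A [scene_params()].
#' @return A `"thermal_scene"`: `frames` (list of integer grey matrices),
#'   `truth`, `layout` (a [bar_layout()] or `NULL`), `params`.
#' @examples
#' sc <- simulate_thermal_sequence(scene_params(duration = 10, seed = 7))
#' length(sc$frames)
#' @export
simulate_thermal_sequence <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  n <- params$n_frames
  layout <- if (params$include_bar) bar_layout(params$frame_shape) else NULL
  img_shape <- if (is.null(layout)) {
    params$frame_shape
  } else {
    c(layout$image_box$r1 - layout$image_box$r0, params$frame_shape[2])
  }
  path <- resolve_mouth_path(params, img_shape)
  t <- (seq_len(n) - 1L) / params$fs
  mouth_mean <- params$base_temp + params$temp_drift_rate * t / 60 +
    params$breath_amplitude * sin(2 * pi * params$breath_freq * t)
  rois <- lapply(seq_len(n), function(i) patch_roi(path[i, ], params$mouth_size))
  ok <- vapply(rois, roi_in_frame, logical(1), dim = img_shape)
  if (!all(ok)) abort("mouth patch exceeds frame bounds along the trajectory")

  base <- face_field(img_shape)
  frames <- vector("list", n)
  tmin <- numeric(n); tmax <- numeric(n)
  withr::with_seed(params$seed, {
    for (i in seq_len(n)) {
      temp <- base
      temp[roi_rows(rois[[i]]), roi_cols(rois[[i]])] <- mouth_mean[i]
      if (params$noise_std > 0) {
        temp <- temp + rnorm(length(temp), sd = params$noise_std)
      }
      lo <- floor(min(temp) * 10) / 10
      hi <- ceiling(max(temp) * 10) / 10
      if (hi - lo < 0.1) hi <- lo + 0.1
      grey <- pmin(255L, pmax(0L, as.integer(round(255 * (temp - lo) / (hi - lo)))))
      img <- matrix(grey, img_shape[1], img_shape[2])
      frames[[i]] <- if (is.null(layout)) {
        img
      } else {
        rbind(render_calibration_bar(lo, hi, layout), img)
      }
      tmin[i] <- lo; tmax[i] <- hi
    }
  })
  structure(
    list(frames = frames,
         truth = list(breath_freq = params$breath_freq, time = t,
                      mouth_roi = rois, mean_mouth_temp = mouth_mean,
                      tmin = tmin, tmax = tmax),
         layout = layout, params = params),
    class = "thermal_scene"
  )
}

#' Simulate a depth (chest-motion) video
#'
#' Per-frame distance matrices in metres: a background plane, a nearer body
#' blob, and a fixed chest patch at
#' `chest_mean_dist + chest_amplitude * sin(2 pi f t)` with Gaussian noise.
#' All values are clamped to the 0.4-4 m sensor range.
#'
#' @param params A [scene_params()].
#' @return A `"depth_scene"`: `frames` (list of numeric matrices), `truth`
#'   (`chest_dist` closed-form series, `chest_roi`, `time`), `params`.
#' @export
simulate_depth_sequence <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  n <- params$n_frames
  shape <- params$depth_frame_shape
  croi <- params$chest_roi
  if (is.null(croi)) {
    croi <- roi(round(shape[1] * 0.35), round(shape[2] * 0.35),
                round(shape[1] * 0.35) + max(8L, shape[1] %/% 4),
                round(shape[2] * 0.35) + max(10L, shape[2] %/% 4))
  }
  if (!roi_in_frame(croi, shape)) abort("chest ROI exceeds depth frame bounds")
  t <- (seq_len(n) - 1L) / params$fs
  chest <- params$chest_mean_dist +
    params$chest_amplitude * sin(2 * pi * params$breath_freq * t)

  r <- matrix(seq_len(shape[1]) - 1L, shape[1], shape[2])
  c <- matrix(seq_len(shape[2]) - 1L, shape[1], shape[2], byrow = TRUE)
  body <- exp(-((r - 0.5 * shape[1])^2 / (2 * (shape[1] / 3)^2) +
                  (c - 0.5 * shape[2])^2 / (2 * (shape[2] / 3)^2)))
  base <- 2.6 - (2.6 - params$chest_mean_dist) * body

  frames <- vector("list", n)
  withr::with_seed(params$seed + 1L, {
    for (i in seq_len(n)) {
      d <- base
      d[roi_rows(croi), roi_cols(croi)] <- chest[i]
      if (params$depth_noise_std > 0) {
        d <- d + rnorm(length(d), sd = params$depth_noise_std)
      }
      frames[[i]] <- matrix(pmin(4, pmax(0.4, d)), shape[1], shape[2])
    }
  })
  structure(
    list(frames = frames,
         truth = list(breath_freq = params$breath_freq, time = t,
                      chest_dist = chest, chest_roi = croi),
         params = params),
    class = "depth_scene"
  )
}

#' Glyph jitter parameters
#'
#' Random perturbations applied to rendered glyphs when building OCR training
#' data: integer pixel shifts, isotropic scaling, and additive grey noise.
#'
#' @param shift_px Maximum absolute shift, px (rows and columns).
#' @param scale_range Range of the scale factor. The default never scales
#'   below 1: the base font is already at its minimum legible raster size
#'   (5x7), and shrinking it deletes strokes no reader could recover.
#' @param noise_sd Grey-level noise standard deviation (0-255 scale).
#' @export
jitter_params <- function(shift_px = 1L, scale_range = c(0.95, 1.1),
                          noise_sd = 15) {
  stopifnot(shift_px >= 0, noise_sd >= 0, scale_range[1] <= scale_range[2])
  structure(list(shift_px = shift_px, scale_range = scale_range,
                 noise_sd = noise_sd), class = "jitter_params")
}

#' Build a labelled digit-glyph training set
#'
#' Renders `n_per_class` jittered copies of every bar character (digits,
#' decimal point, minus sign) with the same raster font the calibration bar
#' uses.
#'
#' @param n_per_class Renderings per character class (>= 1).
#' @param jitter A [jitter_params()].
#' @param seed Integer seed; output is deterministic given the seed.
#' @param chars Character classes to render.
#' @param cell_shape Cell size `(rows, cols)` in px.
#' @return List with `glyphs` (list of grey matrices) and `labels`
#'   (character vector), balanced across classes.
#' @export
make_digit_training_set <- function(n_per_class, jitter = jitter_params(),
                                    seed = 1L, chars = bar_charset(),
                                    cell_shape = c(11L, 6L)) {
  stopifnot(n_per_class >= 1)
  labels <- rep(chars, each = n_per_class)
  glyphs <- withr::with_seed(as.integer(seed), {
    lapply(labels, function(ch) {
      sh <- if (jitter$shift_px > 0) {
        sample(seq(-jitter$shift_px, jitter$shift_px), 2, replace = TRUE)
      } else {
        c(0L, 0L)
      }
      sc <- runif(1, jitter$scale_range[1], jitter$scale_range[2])
      g <- render_glyph_cell(ch, cell_shape = cell_shape, shift = sh, scale = sc)
      if (jitter$noise_sd > 0) {
        g <- pmin(255, pmax(0, g + rnorm(length(g), sd = jitter$noise_sd)))
      }
      matrix(g, cell_shape[1], cell_shape[2])
    })
  })
  list(glyphs = glyphs, labels = labels)
}
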