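#' Mouth-ROI tracking parameters
#'
#' Controls the temperature-change detection of the breathing region. The
#' change map is the per-pixel peak-to-peak temperature over a trailing
#' history window, box-smoothed; it is thresholded at a high quantile and the
#' surviving 8-connected components are screened by area.
#'
#' @param history_sec Trailing window length, s (usable range 1-8 s).
#'   Default 2 s: long enough to span at least half a breath cycle at
#'   the slow end of the band, short enough that head motion of up to
#'   1 px/frame does not smear the change map far beyond the mouth.
#' @param init_frames Frames used for the initial detection; defaults to one
#'   history window.
#' @param change_quantile Quantile of the change map used as threshold.
#' @param min_area,max_area Component area bounds, px.
#' @param smoothing_radius Box-smoothing radius applied to the change map, px.
#' @return A `"roi_track_params"`.
#' @export
roi_track_params <- function(history_sec = 2, init_frames = NULL,
                             change_quantile = 0.95, min_area = 9L,
                             max_area = Inf, smoothing_radius = 1L) {
  if (history_sec < 1 || history_sec > 8) {
    abort("history_sec must lie between 1 and 8 s")
  }
  if (change_quantile <= 0 || change_quantile >= 1) {
    abort("change_quantile must lie strictly between 0 and 1")
  }
  if (min_area < 1 || max_area < min_area) abort("need 1 <= min_area <= max_area")
  structure(list(history_sec = history_sec, init_frames = init_frames,
                 change_quantile = change_quantile, min_area = min_area,
                 max_area = max_area, smoothing_radius = as.integer(smoothing_radius)),
            class = "roi_track_params")
}

# exact box mean filter (window (2r+1)^2, renormalised at the borders),
# via an integral image
box_smooth <- function(m, radius) {
  radius <- as.integer(radius)
  if (radius <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  cs <- matrix(0, nr + 1L, nc + 1L)
  cs[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  r1 <- pmax(seq_len(nr) - radius, 1L); r2 <- pmin(seq_len(nr) + radius, nr)
  c1 <- pmax(seq_len(nc) - radius, 1L); c2 <- pmin(seq_len(nc) + radius, nc)
  tot <- cs[r2 + 1L, c2 + 1L] - cs[r1, c2 + 1L] - cs[r2 + 1L, c1] + cs[r1, c1]
  tot / outer(r2 - r1 + 1L, c2 - c1 + 1L)
}

#' Temperature-change map of a frame window
#'
#' Per-pixel peak-to-peak (max minus min) temperature over the window,
#' optionally box-smoothed. Pixels over the breathing region show the
#' largest changes.
#'
#' @param temp_frames List of equally shaped temperature matrices (>= 2).
#' @param smoothing_radius Box-smoothing radius, px (0 = none).
#' @return Non-negative matrix of the window's temperature excursions.
#' @export
change_map <- function(temp_frames, smoothing_radius = 0L) {
  if (length(temp_frames) < 2) abort("change map needs at least two frames")
  dims <- lapply(temp_frames, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    abort("frames must share a common shape")
  }
  rng <- Reduce(pmax, temp_frames) - Reduce(pmin, temp_frames)
  box_smooth(rng, smoothing_radius)
}

# 8-connected components of a logical mask, by min-label propagation on the
# sparse set of TRUE pixels. Returns a list of components, each with 0-based
# pixel rows/cols, area, bounding-box roi and pixel centroid.
label_components <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0) return(list())
  nr <- nrow(mask); ncc <- ncol(mask)
  r <- (idx - 1L) %% nr
  c <- (idx - 1L) %/% nr
  key <- idx - 1L
  nb <- matrix(NA_integer_, length(idx), 8L)
  k <- 0L
  for (dr in -1L:1L) for (dc in -1L:1L) {
    if (dr == 0L && dc == 0L) next
    k <- k + 1L
    rr <- r + dr; cc <- c + dc
    ok <- rr >= 0L & rr < nr & cc >= 0L & cc < ncc
    mm <- rep(NA_integer_, length(idx))
    mm[ok] <- match(cc[ok] * nr + rr[ok], key)
    nb[, k] <- mm
  }
  lab <- seq_along(idx)
  repeat {
    new <- lab
    for (k in 1:8) {
      v <- nb[, k]; ok <- !is.na(v)
      new[ok] <- pmin(new[ok], lab[v[ok]])
    }
    if (identical(new, lab)) break
    lab <- new
  }
  lapply(unname(split(seq_along(idx), lab)), function(i) {
    list(rows = r[i], cols = c[i], area = length(i),
         box = roi(min(r[i]), min(c[i]), max(r[i]) + 1L, max(c[i]) + 1L),
         centroid = c(mean(r[i]) + 0.5, mean(c[i]) + 0.5))
  })
}

detection_error <- function(msg) abort(msg, class = "breathcam_detection_error")

# threshold a change map and pick a component; prev = NULL selects the
# largest qualifying component, otherwise the one nearest prev's centre
select_roi_from_change <- function(cm, params, prev = NULL) {
  thr <- quantile(cm, params$change_quantile, names = FALSE)
  comps <- label_components(cm > thr)
  comps <- keep(comps, ~ .x$area >= params$min_area && .x$area <= params$max_area)
  if (length(comps) == 0) {
    if (is.null(prev)) {
      detection_error("no connected change region within the area bounds")
    }
    return(structure(prev, fallback = TRUE))
  }
  if (is.null(prev)) {
    ord <- order(-map_dbl(comps, "area"),
                 map_dbl(comps, ~ .x$box$r0), map_dbl(comps, ~ .x$box$c0))
  } else {
    ctr <- roi_centroid(prev)
    d <- map_dbl(comps, ~ sqrt(sum((.x$centroid - ctr)^2)))
    ord <- order(d, -map_dbl(comps, "area"),
                 map_dbl(comps, ~ .x$box$r0), map_dbl(comps, ~ .x$box$c0))
  }
  structure(comps[[ord[1]]]$box, fallback = FALSE)
}

#' Detect the initial breathing ROI
#'
#' Thresholds the change map of the first frames at `change_quantile` and
#' returns the bounding box of the largest 8-connected component within the
#' area bounds. Raises a detection error (class
#' `"breathcam_detection_error"`) when no component qualifies, e.g. on a
#' static scene.
#'
#' @param temp_frames The first `init_frames` temperature matrices (>= 2).
#' @param params A [roi_track_params()].
#' @return An [roi()].
#' @export
detect_initial_roi <- function(temp_frames, params = roi_track_params()) {
  cm <- change_map(temp_frames, params$smoothing_radius)
  select_roi_from_change(cm, params, prev = NULL)
}

#' Update the breathing ROI from a trailing window
#'
#' Same detection as [detect_initial_roi()], but among qualifying components
#' the one whose centroid lies nearest the previous ROI's centre wins (ties:
#' larger area, then lower corner). When nothing qualifies the previous ROI
#' is returned unchanged with `attr(, "fallback") = TRUE`, keeping the
#' temperature series gap-free.
#'
#' @param prev The previous [roi()].
#' @param temp_frames Trailing window of `history_sec * fs` frames.
#' @param params A [roi_track_params()].
#' @return An [roi()] with a `fallback` attribute.
#' @export
update_roi <- function(prev, temp_frames, params = roi_track_params()) {
  cm <- change_map(temp_frames, params$smoothing_radius)
  select_roi_from_change(cm, params, prev = prev)
}

# sliding min and max over trailing windows of length h along columns of X
# (pixels x time), by the two-block prefix/suffix decomposition; columns
# t < h are NA (truncated windows are never requested by the tracker)
slide_range <- function(X, h) {
  n <- ncol(X); npx <- nrow(X)
  out_min <- matrix(NA_real_, npx, n)
  out_max <- matrix(NA_real_, npx, n)
  starts <- seq(1L, n, by = h)
  prev_suf_min <- NULL; prev_suf_max <- NULL; prev_s <- NA_integer_
  for (s in starts) {
    e <- min(s + h - 1L, n)
    w <- e - s + 1L
    pre_min <- X[, s:e, drop = FALSE]; pre_max <- pre_min
    if (w > 1) for (j in 2:w) {
      pre_min[, j] <- pmin(pre_min[, j], pre_min[, j - 1L])
      pre_max[, j] <- pmax(pre_max[, j], pre_max[, j - 1L])
    }
    suf_min <- X[, s:e, drop = FALSE]; suf_max <- suf_min
    if (w > 1) for (j in (w - 1L):1L) {
      suf_min[, j] <- pmin(suf_min[, j], suf_min[, j + 1L])
      suf_max[, j] <- pmax(suf_max[, j], suf_max[, j + 1L])
    }
    for (t in s:e) {
      l <- t - h + 1L
      if (l < 1L) next
      j <- t - s + 1L
      if (l >= s) {
        out_min[, t] <- pre_min[, j]
        out_max[, t] <- pre_max[, j]
      } else {
        jp <- l - prev_s + 1L
        out_min[, t] <- pmin(prev_suf_min[, jp], pre_min[, j])
        out_max[, t] <- pmax(prev_suf_max[, jp], pre_max[, j])
      }
    }
    prev_suf_min <- suf_min; prev_suf_max <- suf_max; prev_s <- s
  }
  list(min = out_min, max = out_max)
}

#' Track the breathing ROI through a sequence
#'
#' Detects the initial ROI on the first `init_frames` frames, then re-detects
#' it for every subsequent frame from the trailing `history_sec` window,
#' following slow head movement. Frames where detection fails keep the
#' previous ROI and are flagged.
#'
#' @param temp_frames List of temperature matrices (image region, degC).
#' @param fs Sampling frequency, Hz.
#' @param params A [roi_track_params()].
#' @param fixed_roi Optional fallback [roi()] used if even the initial
#'   detection fails.
#' @return A `"roi_trace"` tibble with 0-based `frame_index`, `time_s`, the
#'   per-frame ROI corners, `mean_temp` (degC), `roi_area` (px) and a
#'   `fallback` flag.
#' @export
track_mouth_roi <- function(temp_frames, fs, params = roi_track_params(),
                            fixed_roi = NULL) {
  n <- length(temp_frames)
  h <- max(2L, as.integer(round(params$history_sec * fs)))
  init_f <- as.integer(params$init_frames %||% h)
  if (init_f < 2L) abort("init_frames must be at least 2")
  if (n < init_f) abort("sequence shorter than the initial detection window")

  first <- tryCatch(
    structure(detect_initial_roi(temp_frames[seq_len(init_f)], params),
              fallback = FALSE),
    breathcam_detection_error = function(e) {
      if (is.null(fixed_roi)) stop(e)
      structure(fixed_roi, fallback = TRUE)
    }
  )

  rois <- vector("list", n)
  fallback <- logical(n)
  for (i in seq_len(min(init_f, n))) {
    rois[[i]] <- first
    fallback[i] <- attr(first, "fallback")
  }
  if (n > init_f) {
    npx <- length(temp_frames[[1]])
    shape <- dim(temp_frames[[1]])
    X <- matrix(unlist(temp_frames, use.names = FALSE), npx, n)
    sr <- slide_range(X, h)
    prev <- first
    for (i in (init_f + 1L):n) {
      cm <- matrix(sr$max[, i] - sr$min[, i], shape[1], shape[2])
      cm <- box_smooth(cm, params$smoothing_radius)
      cur <- select_roi_from_change(cm, params, prev = prev)
      rois[[i]] <- cur
      fallback[i] <- attr(cur, "fallback")
      prev <- cur
    }
  }
  out <- tibble(
    frame_index = seq_len(n) - 1L,
    time_s = (seq_len(n) - 1L) / fs,
    r0 = map_int(rois, "r0"), c0 = map_int(rois, "c0"),
    r1 = map_int(rois, "r1"), c1 = map_int(rois, "c1"),
    mean_temp = vapply(seq_len(n), function(i) {
      mean_temperature(temp_frames[[i]], rois[[i]])
    }, numeric(1)),
    roi_area = map_int(rois, roi_area),
    fallback = fallback
  )
  structure(out, fs = fs, params = params,
            class = c("roi_trace", class(out)))
}

#' Mean temperature over an ROI
#'
#' @param frame Temperature matrix, degC.
#' @param roi An [roi()] inside the frame.
#' @return Arithmetic mean, degC.
#' @export
mean_temperature <- function(frame, roi) {
  mean(roi_crop(frame, roi))
}

#' Percentage of ROI pixels inside a temperature range
#'
#' The stationarity / precision statistic: the share of ROI pixels whose
#' temperature falls within `[t_low, t_high]` (e.g. the 26-28 degC band used
#' for camera-precision assessment), as a percentage of the ROI area.
#'
#' @param frame Temperature matrix, degC.
#' @param roi An [roi()].
#' @param t_low,t_high Band edges, degC, `t_low < t_high`.
#' @return Percentage in `[0, 100]`.
#' @export
range_fraction <- function(frame, roi, t_low, t_high) {
  if (!(t_low < t_high)) abort("need t_low < t_high")
  v <- roi_crop(frame, roi)
  100 * sum(v >= t_low & v <= t_high) / length(v)
}

#' Flat-field summary statistics
#'
#' Pixel-value distribution summary of a single frame, for assessing camera
#' accuracy on a surface of uniform temperature.
#'
#' @param frame Temperature matrix, degC.
#' @return One-row tibble: `mean`, `sd`, `min`, `max`, `n_px`.
#' @export
flat_field_stats <- function(frame) {
  if (length(frame) == 0) abort("empty frame")
  tibble(mean = mean(frame), sd = stats::sd(as.numeric(frame)),
         min = min(frame), max = max(frame), n_px = length(frame))
}

#' Extract the breathing temperature series
#'
#' Per-frame mean temperature over either a fixed ROI or a tracked
#' [track_mouth_roi()] trace.
#'
#' @param temp_frames List of temperature matrices.
#' @param roi An [roi()] (fixed) or a `"roi_trace"` (moving).
#' @param fs Sampling frequency, Hz.
#' @return A [breath_signal()] tibble in degC.
#' @export
extract_thermal_series <- function(temp_frames, roi, fs) {
  if (inherits(roi, "roi_trace")) {
    stopifnot(nrow(roi) == length(temp_frames))
    breath_signal(roi$mean_temp, fs, unit = "degC")
  } else {
    x <- vapply(temp_frames, mean_temperature, numeric(1), roi = roi)
    breath_signal(x, fs, unit = "degC")
  }
}
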