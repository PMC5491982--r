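#' Mean chest distance over an ROI
#'
#' Arithmetic mean of the valid depth pixels inside the ROI. Pixels outside
#' the sensor range or non-finite (real range cameras emit zeros/NaN where
#' no return was measured) are excluded and counted.
#'
#' @param frame Depth matrix, metres.
#' @param roi An [roi()] inside the frame.
#' @param sensor_range Valid distance interval, m.
#' @return Mean distance in metres, with attribute `n_invalid`.
#' @export
mean_distance <- function(frame, roi, sensor_range = c(0.4, 4)) {
  v <- roi_crop(frame, roi)
  ok <- is.finite(v) & v >= sensor_range[1] & v <= sensor_range[2]
  if (!any(ok)) abort("all ROI pixels invalid", class = "breathcam_depth_error")
  structure(mean(v[ok]), n_invalid = sum(!ok))
}

#' Extract the chest-motion breathing series
#'
#' Per-frame mean distance of a fixed chest ROI from the depth sensor.
#'
#' @param frames List of depth matrices, metres.
#' @param roi Fixed chest [roi()].
#' @param fs Sampling frequency, Hz.
#' @param sensor_range Valid distance interval, m.
#' @return A [breath_signal()] tibble in metres with an `n_invalid` column.
#' @export
extract_depth_series <- function(frames, roi, fs, sensor_range = c(0.4, 4)) {
  if (length(frames) == 0) abort("empty depth sequence")
  vals <- numeric(length(frames))
  n_invalid <- integer(length(frames))
  for (i in seq_along(frames)) {
    m <- tryCatch(mean_distance(frames[[i]], roi, sensor_range),
                  breathcam_depth_error = function(e) {
                    abort(sprintf("frame %d: %s", i - 1L, conditionMessage(e)),
                          class = "breathcam_depth_error")
                  })
    vals[i] <- m
    n_invalid[i] <- attr(m, "n_invalid")
  }
  out <- breath_signal(vals, fs, unit = "m")
  out$n_invalid <- n_invalid
  out
}
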