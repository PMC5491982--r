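#' Temperature scale of one thermal frame
#'
#' The grey-to-temperature mapping read from a frame's calibration bar:
#' grey 0 corresponds to `tmin`, grey 255 to `tmax`.
#'
#' @param tmin,tmax Frame minimum / maximum temperature, degC, `tmin < tmax`.
#' @return A `"temperature_scale"`.
#' @export
temperature_scale <- function(tmin, tmax) {
  if (!is.finite(tmin) || !is.finite(tmax) || tmin >= tmax) {
    abort("need finite tmin < tmax", class = "breathcam_calibration_error")
  }
  structure(list(tmin = tmin, tmax = tmax, grey_levels = c(0L, 255L)),
            class = "temperature_scale")
}

#' @export
print.temperature_scale <- function(x, ...) {
  cat(sprintf("<temperature_scale> %.1f .. %.1f degC over grey 0..255\n",
              x$tmin, x$tmax))
  invisible(x)
}

calibration_error <- function(msg, frame_index = NULL) {
  if (!is.null(frame_index)) msg <- sprintf("frame %d: %s", frame_index, msg)
  abort(msg, class = "breathcam_calibration_error", frame_index = frame_index)
}

# Read one printed temperature field. Every cell is classified; the blank
# class " " covers the sign position of positive values (fields are fixed
# width), and is only legal before the first printable character. A cell
# whose top softmax probability falls below `reject` is a calibration
# failure.
read_bar_field <- function(frame, cells, model, reject, frame_index = NULL) {
  pred <- classify_glyphs(model, lapply(cells, function(b) roi_crop(frame, b)))
  low <- which(pred$confidence < reject)
  if (length(low) > 0) {
    calibration_error(sprintf("unrecognised glyph in cell %d (confidence %.2f)",
                              low[1], pred$confidence[low[1]]), frame_index)
  }
  chars <- ifelse(pred$label == " ", "", pred$label)
  nonblank <- which(chars != "")
  if (length(nonblank) == 0) calibration_error("temperature field is blank", frame_index)
  if (any(chars[min(nonblank):length(chars)] == "")) {
    calibration_error("blank cell inside a temperature field", frame_index)
  }
  value <- suppressWarnings(as.numeric(paste(chars, collapse = "")))
  if (is.na(value)) {
    calibration_error(sprintf("unparseable temperature field '%s'",
                              paste(chars, collapse = "")), frame_index)
  }
  value
}

#' Read the temperature range printed in a frame's calibration bar
#'
#' Classifies every character cell of the min and max temperature fields with
#' the digit network and parses the two values (sign, digits, decimal point).
#'
#' @param frame Integer grey matrix of the full thermal frame.
#' @param layout The frame's [bar_layout()].
#' @param model A [train_digit_classifier()] fit.
#' @param reject Minimum softmax confidence accepted per character cell.
#' @param frame_index Optional index carried into error conditions.
#' @return A [temperature_scale()].
#' @examples
#' lay <- bar_layout(c(56, 80))
#' @export
read_calibration_bar <- function(frame, layout, model, reject = 0.5,
                                 frame_index = NULL) {
  stopifnot(inherits(layout, "bar_layout"), inherits(model, "digit_classifier"))
  cells <- c(layout$min_cells, layout$max_cells)
  ok <- vapply(cells, roi_in_frame, logical(1), dim = dim(frame))
  if (!all(ok)) abort("bar layout cells extend outside the frame")
  tmin <- read_bar_field(frame, layout$min_cells, model, reject, frame_index)
  tmax <- read_bar_field(frame, layout$max_cells, model, reject, frame_index)
  if (tmin >= tmax) {
    calibration_error(sprintf("read tmin %.1f >= tmax %.1f", tmin, tmax), frame_index)
  }
  temperature_scale(tmin, tmax)
}

#' Map grey levels to temperatures
#'
#' The affine per-frame calibration `T = tmin + g * (tmax - tmin) / 255`.
#'
#' @param grey Integer grey matrix (0-255).
#' @param scale A [temperature_scale()].
#' @return Numeric temperature matrix, degC.
#' @examples
#' grey_to_temperature(matrix(128, 2, 2), temperature_scale(20, 30))
#' @export
grey_to_temperature <- function(grey, scale) {
  stopifnot(inherits(scale, "temperature_scale"))
  if (any(grey < 0 | grey > 255)) abort("grey values must lie in 0..255")
  scale$tmin + grey * (scale$tmax - scale$tmin) / 255
}

#' Calibrate a thermal frame sequence
#'
#' Reads each frame's calibration bar, converts the image region below the
#' bar to temperatures, and tabulates the per-frame spans.
#'
#' @param frames List of full-frame grey matrices.
#' @param layout A [bar_layout()].
#' @param model A [train_digit_classifier()] fit.
#' @param reject Per-cell confidence threshold.
#' @return List with `temps` (temperature matrices of the image region) and
#'   `scales`, a tibble `(frame_index, tmin, tmax)` with 0-based indices.
#' @export
calibrate_frames <- function(frames, layout, model, reject = 0.5) {
  n <- length(frames)
  temps <- vector("list", n)
  tmin <- numeric(n); tmax <- numeric(n)
  for (i in seq_len(n)) {
    sc <- read_calibration_bar(frames[[i]], layout, model, reject,
                               frame_index = i - 1L)
    temps[[i]] <- grey_to_temperature(roi_crop(frames[[i]], layout$image_box), sc)
    tmin[i] <- sc$tmin; tmax[i] <- sc$tmax
  }
  list(temps = temps,
       scales = tibble(frame_index = seq_len(n) - 1L, tmin = tmin, tmax = tmax))
}
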