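#' Plot a breathing series
#'
#' @param object A [breath_signal()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot breath_signal
#' @export
autoplot.breath_signal <- function(object, ...) {
  unit <- attr(object, "unit") %||% ""
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(x = "time [s]",
                  y = if (nzchar(unit)) paste0("value [", unit, "]") else "value",
                  title = "Breathing series") +
    ggplot2::theme_minimal()
}

#' Plot a breathing spectrum
#'
#' DFT magnitudes up to the Nyquist frequency with the analysis band shaded.
#'
#' @param object A [dft_spectrum()].
#' @param f_low,f_high Analysis band to highlight, Hz.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot breath_spectrum
#' @export
autoplot.breath_spectrum <- function(object, f_low = 0.05, f_high = 1.5, ...) {
  fs <- attr(object, "fs")
  half <- dplyr::filter(as_tibble(object), .data$freq_hz <= fs / 2)
  ggplot2::ggplot(half, ggplot2::aes(x = .data$freq_hz, y = .data$magnitude)) +
    ggplot2::annotate("rect", xmin = f_low, xmax = f_high, ymin = -Inf,
                      ymax = Inf, alpha = 0.12, fill = "#b2182b") +
    ggplot2::geom_line(colour = "grey20") +
    ggplot2::labs(x = "frequency [Hz]", y = "|Y(k)|",
                  title = "Breathing spectrum") +
    ggplot2::theme_minimal()
}

#' Plot a mouth-ROI trace
#'
#' Mean ROI temperature over time; the dot size follows the currently
#' detected mouth area and fallback frames are marked.
#'
#' @param object A [track_mouth_roi()] trace.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot roi_trace
#' @export
autoplot.roi_trace <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$mean_temp)) +
    ggplot2::geom_line(colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(size = .data$roi_area,
                                     colour = .data$fallback), alpha = 0.6) +
    ggplot2::scale_size_area(max_size = 3) +
    ggplot2::scale_colour_manual(values = c("FALSE" = "#2166ac", "TRUE" = "#b2182b")) +
    ggplot2::labs(x = "time [s]", y = "mean ROI temperature [degC]",
                  title = "Adaptive mouth-ROI temperature trace") +
    ggplot2::theme_minimal()
}

#' Plot windowed breathing features
#'
#' Per-window mean value and breathing frequency over time.
#'
#' @param object A [windowed_features()] tibble.
#' @param ... Unused.
#' @return A ggplot (two facets).
#' @method autoplot windowed_features
#' @export
autoplot.windowed_features <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("mean_value", "freq_bpm"),
                              names_to = "feature")
  long$feature <- factor(long$feature, c("mean_value", "freq_bpm"),
                         c("window mean", "breathing rate [bpm]"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_center, y = .data$value)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~feature, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "window centre [s]", y = NULL,
                  title = "Windowed breathing features") +
    ggplot2::theme_minimal()
}
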