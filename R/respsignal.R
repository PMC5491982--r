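#' Uniformly sampled breathing series
#'
#' The scalar record `{x(n)}, n = 0..N-1` that both sensors produce: mouth
#' mean temperature (degC) from the thermal camera, or chest mean distance
#' (m) from the depth sensor.
#'
#' @param x Numeric samples, all finite, `N >= 2`.
#' @param fs Sampling frequency, Hz.
#' @param unit Measurement unit label.
#' @return A `"breath_signal"` tibble with `time` (s) and `value` columns and
#'   attributes `fs`, `unit`.
#' @export
breath_signal <- function(x, fs, unit = "") {
  x <- as.numeric(x)
  if (length(x) < 2) abort("breath signal needs at least two samples")
  if (!all(is.finite(x))) abort("breath signal samples must be finite")
  if (!is.finite(fs) || fs <= 0) abort("fs must be positive")
  out <- tibble(time = (seq_along(x) - 1) / fs, value = x)
  structure(out, fs = fs, unit = unit,
            class = c("breath_signal", class(out)))
}

signal_fs <- function(x) {
  fs <- attr(x, "fs")
  if (is.null(fs)) abort("not a breath_signal: missing fs attribute")
  fs
}

#' Design the breathing band-pass filter
#'
#' Linear-phase FIR band-pass by windowed-sinc (Hamming) design, targeting
#' the breathing band of 0.05-1.5 Hz. The realised magnitude response is
#' verified: at least -6 dB across `[2 f_low, 0.8 f_high]` and at most
#' -20 dB at DC and at the Nyquist frequency; a design failing verification
#' errors.
#'
#' @param f_low,f_high Band edges, Hz, `0 < f_low < f_high < fs/2`.
#' @param taps Filter length M (number of coefficients).
#' @param fs Sampling frequency, Hz.
#' @param verify Check the realised response and error when the band cannot
#'   be met? Internal short-window de-noising filters skip this (their
#'   inputs are mean-removed, so DC suppression is not load-bearing).
#' @return A `"filter_spec"`: coefficients `b` (length `M`, symmetric), `M`,
#'   band edges and `fs`.
#' @examples
#' spec <- design_bandpass(0.05, 1.5, taps = 512, fs = 10)
#' abs(sum(spec$b))   # DC gain, ~0
#' @export
design_bandpass <- function(f_low = 0.05, f_high = 1.5, taps = 512L, fs = 10,
                            verify = TRUE) {
  if (!(taps >= 1)) abort("need at least one tap")
  if (!(0 < f_low && f_low < f_high && f_high < fs / 2)) {
    abort("need 0 < f_low < f_high < fs/2")
  }
  b <- as.numeric(signal::fir1(as.integer(taps) - 1L,
                               c(f_low, f_high) / (fs / 2), type = "pass"))
  gain <- function(f) {
    k <- seq_along(b) - 1
    vapply(f, function(ff) abs(sum(b * exp(-1i * 2 * pi * ff * k / fs))), numeric(1))
  }
  band <- seq(2 * f_low, 0.8 * f_high, length.out = 25)
  ok <- all(gain(band) >= 10^(-6 / 20)) &&
    all(gain(c(0, fs / 2)) <= 10^(-20 / 20))
  if (verify && !ok) {
    abort(sprintf("band-pass design infeasible: %d taps cannot realise [%g, %g] Hz at fs %g",
                  taps, f_low, f_high, fs), class = "breathcam_design_error")
  }
  structure(list(b = b, M = length(b), f_low = f_low, f_high = f_high, fs = fs),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> FIR band-pass %g-%g Hz, %d taps at fs %g Hz\n",
              x$f_low, x$f_high, x$M, x$fs))
  invisible(x)
}

#' Apply an FIR filter
#'
#' Causal convolution `y(n) = sum_k b(k) x(n-k)` with zero initial
#' conditions; the output has the input's length.
#'
#' @param signal A [breath_signal()] (or numeric vector).
#' @param spec A [design_bandpass()] `"filter_spec"` or a numeric coefficient
#'   vector.
#' @return A filtered object of the same kind as the input.
#' @export
fir_filter <- function(signal, spec) {
  b <- if (inherits(spec, "filter_spec")) spec$b else as.numeric(spec)
  if (length(b) < 1 || !all(is.finite(b))) abort("invalid filter coefficients")
  x <- if (inherits(signal, "breath_signal")) signal$value else as.numeric(signal)
  y <- as.numeric(signal::filter(b, 1, x))
  if (inherits(signal, "breath_signal")) {
    out <- signal
    out$value <- y
    out
  } else {
    y
  }
}

#' Discrete Fourier transform of a breathing series
#'
#' `Y(k) = sum_n y(n) exp(-j k n 2 pi / N)` for `k = 0..N-1`, with bin `k`
#' mapped to frequency `f_k = (k / N) fs`.
#'
#' @param signal A [breath_signal()] or numeric vector (then `fs` must be
#'   given).
#' @param fs Sampling frequency, Hz, when `signal` is a bare vector.
#' @return A `"breath_spectrum"` tibble: `k`, `freq_hz`, complex `Y` and
#'   `magnitude`, with attributes `fs` and `n`.
#' @export
dft_spectrum <- function(signal, fs = NULL) {
  x <- if (inherits(signal, "breath_signal")) signal$value else as.numeric(signal)
  fs <- if (inherits(signal, "breath_signal")) signal_fs(signal) else fs
  if (is.null(fs)) abort("fs required for a bare numeric signal")
  n <- length(x)
  if (n < 2) abort("DFT needs at least two samples")
  Y <- fft(x)
  out <- tibble(k = seq_len(n) - 1L,
                freq_hz = (seq_len(n) - 1L) / n * fs,
                Y = Y, magnitude = Mod(Y))
  structure(out, fs = fs, n = n,
            class = c("breath_spectrum", class(out)))
}

#' Breathing frequency from a spectrum
#'
#' The bin of largest DFT magnitude within the analysis band (ties resolve
#' to the lowest bin), reported in Hz, breaths per minute and as the bin
#' index. No peak interpolation is applied: the estimate is accurate to the
#' record's frequency resolution `fs / N`.
#'
#' @param spectrum A [dft_spectrum()].
#' @param f_low,f_high Analysis band, Hz.
#' @return One-row tibble: `freq_hz`, `freq_bpm`, `bin`.
#' @export
breathing_frequency <- function(spectrum, f_low = 0.05, f_high = 1.5) {
  stopifnot(inherits(spectrum, "breath_spectrum"))
  fs <- attr(spectrum, "fs"); n <- attr(spectrum, "n")
  in_band <- spectrum$freq_hz >= f_low & spectrum$freq_hz <= f_high &
    spectrum$freq_hz <= fs / 2
  if (!any(in_band)) abort("no DFT bin inside the analysis band")
  sub <- spectrum[in_band, ]
  k <- sub$k[which.max(sub$magnitude)]
  f <- k / n * fs
  tibble(freq_hz = f, freq_bpm = 60 * f, bin = as.integer(k))
}

#' Windowed breathing features
#'
#' Splits the record into non-overlapping windows and reports, per window,
#' the mean of the raw series and the breathing frequency estimated from the
#' band-pass-filtered, mean-removed window.
#'
#' @param signal A [breath_signal()].
#' @param window_len_s Window length, s (default 60 s).
#' @param f_low,f_high Analysis band, Hz.
#' @param taps Filter length used per window; defaults to
#'   `min(512, samples_per_window / 2)` so the startup transient stays well
#'   inside the window.
#' @return A `"windowed_features"` tibble: `window`, `t_center` (s),
#'   `mean_value`, `freq_hz`, `freq_bpm`.
#' @export
windowed_features <- function(signal, window_len_s = 60, f_low = 0.05,
                              f_high = 1.5, taps = NULL) {
  stopifnot(inherits(signal, "breath_signal"))
  fs <- signal_fs(signal)
  w <- as.integer(round(window_len_s * fs))
  if (w < 4) abort("window must contain at least 4 samples")
  n_win <- length(signal$value) %/% w
  if (n_win < 1) abort("series shorter than one window")
  taps <- as.integer(taps %||% min(512L, w %/% 2L))
  spec <- design_bandpass(f_low, f_high, taps = taps, fs = fs, verify = FALSE)
  rows <- lapply(seq_len(n_win), function(i) {
    seg <- signal$value[((i - 1L) * w + 1L):(i * w)]
    filt <- fir_filter(seg - mean(seg), spec)
    bf <- breathing_frequency(dft_spectrum(filt, fs = fs), f_low, f_high)
    tibble(window = i, t_center = ((i - 1L) * w + (w - 1) / 2) / fs,
           mean_value = mean(seg), freq_hz = bf$freq_hz, freq_bpm = bf$freq_bpm)
  })
  out <- bind_rows(rows)
  structure(out, fs = fs, window_len_s = window_len_s,
            unit = attr(signal, "unit"),
            class = c("windowed_features", class(out)))
}

#' Activity schedule
#'
#' Ordered, contiguous segments of physical load and rest, e.g. two 10-min
#' exercise periods each followed by a 10-min rest.
#'
#' @param start_s,end_s Segment bounds, s; segments must be contiguous.
#' @param label `"load"` or `"rest"` per segment.
#' @return An `"activity_schedule"` tibble.
#' @export
activity_schedule <- function(start_s, end_s, label) {
  stopifnot(length(start_s) == length(end_s), length(label) == length(start_s))
  if (!all(label %in% c("load", "rest"))) abort("labels must be 'load' or 'rest'")
  if (!all(end_s > start_s)) abort("segments must have positive length")
  if (length(start_s) > 1 && !all(abs(start_s[-1] - end_s[-length(end_s)]) < 1e-9)) {
    abort("segments must be contiguous and non-overlapping")
  }
  out <- tibble(start_s = start_s, end_s = end_s, label = label)
  structure(out, class = c("activity_schedule", class(out)))
}

#' Recovery regression of a windowed feature
#'
#' Ordinary-least-squares fit of a windowed feature against time over a
#' post-exercise interval; the slope (units per minute) quantifies the
#' recovery rate. `S` is the mean squared residual as a percentage of the
#' squared mean fitted value.
#'
#' @param features A [windowed_features()] tibble.
#' @param interval `(t_start, t_end)` in seconds; windows whose centres fall
#'   inside are used (at least 3).
#' @param value Feature column: `"mean_value"` or `"freq_bpm"`.
#' @return A `"recovery_fit"` with `slope_per_min`, `intercept`, `S_percent`
#'   and the underlying `lm` fit; see [tidy()] / [glance()] methods.
#' @export
recovery_regression <- function(features, interval, value = "mean_value") {
  stopifnot(value %in% names(features))
  sel <- features$t_center >= interval[1] & features$t_center <= interval[2]
  d <- tibble(t_min = features$t_center[sel] / 60, y = features[[value]][sel])
  if (nrow(d) < 3) abort("need at least 3 windows inside the interval")
  if (stats::var(d$t_min) == 0) abort("degenerate interval: no time variance")
  fit <- lm(y ~ t_min, data = d)
  mf <- mean(fitted(fit))
  structure(
    list(slope_per_min = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         S_percent = 100 * mean(residuals(fit)^2) / mf^2,
         n_windows = nrow(d), value = value, interval = interval, fit = fit),
    class = "recovery_fit"
  )
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf("<recovery_fit> %s: slope %.4g per min, S = %.3g%% (%d windows over %g-%g s)\n",
              x$value, x$slope_per_min, x$S_percent, x$n_windows,
              x$interval[1], x$interval[2]))
  invisible(x)
}

#' @method tidy recovery_fit
#' @export
tidy.recovery_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = c("(Intercept)", "t_min"),
         estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @method glance recovery_fit
#' @export
glance.recovery_fit <- function(x, ...) {
  tibble(slope_per_min = x$slope_per_min, S_percent = x$S_percent,
         r.squared = summary(x$fit)$r.squared, n_windows = x$n_windows)
}

#' Response delay of a feature after activity changes
#'
#' For each boundary between consecutive schedule segments: the baseline is
#' the mean of the last two windows before the boundary and the steady level
#' the mean of the last two windows of the new segment; the delay is the
#' time from the boundary until the feature first reaches
#' `baseline + crossing * (steady - baseline)`, linearly interpolating
#' between window centres. If the level is never reached the delay is
#' censored at the segment length.
#'
#' @param features A [windowed_features()] tibble.
#' @param schedule An [activity_schedule()].
#' @param value Feature column to analyse.
#' @param crossing Crossing fraction in (0, 1), default 0.5.
#' @return Tibble: `boundary_s`, `from`, `to`, `delay_s`, `censored`.
#' @export
response_delay <- function(features, schedule, value = "freq_bpm",
                           crossing = 0.5) {
  stopifnot(inherits(schedule, "activity_schedule"), value %in% names(features))
  if (!(crossing > 0 && crossing < 1)) abort("crossing must lie in (0, 1)")
  t <- features$t_center
  y <- features[[value]]
  out <- list()
  for (i in seq_len(nrow(schedule) - 1L)) {
    tb <- schedule$end_s[i]
    seg_end <- schedule$end_s[i + 1L]
    before <- which(t < tb)
    inside <- which(t >= tb & t <= seg_end)
    if (length(before) < 2 || length(inside) < 2) {
      abort("each segment needs at least 2 windows on both sides of a boundary")
    }
    baseline <- mean(y[tail(before, 2)])
    steady <- mean(y[tail(inside, 2)])
    target <- baseline + crossing * (steady - baseline)
    censored <- FALSE
    if (abs(steady - baseline) < 1e-12) {
      delay <- seg_end - tb
      censored <- TRUE
    } else {
      sgn <- sign(steady - baseline)
      tt <- c(tb, t[inside])
      yy <- c(baseline, y[inside])
      reached <- which(sgn * (yy - target) >= 0)
      if (length(reached) == 0) {
        delay <- seg_end - tb
        censored <- TRUE
      } else {
        j <- reached[1]
        if (j == 1) {
          delay <- 0
        } else {
          f <- (target - yy[j - 1]) / (yy[j] - yy[j - 1])
          delay <- tt[j - 1] + f * (tt[j] - tt[j - 1]) - tb
        }
      }
    }
    out[[i]] <- tibble(boundary_s = tb, from = schedule$label[i],
                       to = schedule$label[i + 1L],
                       delay_s = delay, censored = censored)
  }
  bind_rows(out)
}
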