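test_that("the band-pass design suppresses DC and Nyquist while passing the breathing band", {
  spec <- design_bandpass(0.05, 1.5, taps = 512, fs = 10)
  expect_identical(spec$M, 512L)
  expect_lte(abs(sum(spec$b)), 0.1)                       # DC gain
  expect_equal(spec$b, rev(spec$b), tolerance = 1e-12)    # linear phase
  gain <- function(f) {
    k <- 0:(spec$M - 1)
    abs(sum(spec$b * exp(-1i * 2 * pi * f * k / 10)))
  }
  for (f in seq(0.1, 1.2, by = 0.1)) expect_gte(gain(f), 10^(-6 / 20))
  expect_lte(gain(5), 10^(-20 / 20))

  expect_error(design_bandpass(1.5, 0.05), "f_low")
  expect_error(design_bandpass(0.05, 1.5, taps = 32, fs = 10),
               class = "breathcam_design_error")
})

test_that("fir_filter implements the causal convolution exactly", {
  x <- breath_signal(c(1, 1, 1), fs = 1)
  expect_equal(fir_filter(x, c(1))$value, c(1, 1, 1))
  expect_equal(fir_filter(x, c(0.5, 0.5))$value, c(0.5, 1, 1))
  set.seed(7)
  for (i in 1:10) {
    xs <- rnorm(sample(10:50, 1))
    b <- rnorm(sample(2:12, 1))
    expect_equal(fir_filter(xs, b), fir_oracle(b, xs), tolerance = 1e-12)
  }
})

test_that("dft_spectrum matches the definition, is invertible, and conjugate-symmetric", {
  # constant signal: Y(0) = N c, all other bins zero
  sp <- dft_spectrum(rep(3.5, 16), fs = 8)
  expect_equal(sp$magnitude[1], 16 * 3.5, tolerance = 1e-9)
  expect_lte(max(sp$magnitude[-1]), 1e-9)

  # bin-aligned cosine: |Y(75)| = |Y(2925)| = N/2
  n <- 3000
  y <- cos(2 * pi * 75 * (0:(n - 1)) / n)
  spc <- dft_spectrum(y, fs = 10)
  expect_equal(spc$magnitude[76], 1500, tolerance = 1e-6)
  expect_equal(spc$magnitude[2926], 1500, tolerance = 1e-6)
  expect_lte(max(spc$magnitude[-c(76, 2926)]), 1e-6)

  set.seed(11)
  ys <- rnorm(64)
  sp2 <- dft_spectrum(ys, fs = 10)
  expect_lte(max(Mod(sp2$Y - dft_oracle(ys))), 1e-9)
  # inverse reconstruction
  rec <- Re(vapply(0:63, function(nn) {
    mean(sp2$Y * exp(1i * (0:63) * nn * 2 * pi / 64))
  }, complex(1)))
  expect_lte(max(abs(rec - ys)), 1e-9)
  # conjugate symmetry for real input
  expect_lte(max(Mod(sp2$Y[2:64] - Conj(sp2$Y[64:2]))), 1e-9)
})

test_that("breathing_frequency picks the in-band argmax at the documented resolution", {
  n <- 3000; fs <- 10
  t <- (0:(n - 1)) / fs
  sp <- dft_spectrum(sin(2 * pi * 0.25 * t), fs = fs)
  expect_equal(diff(sp$freq_hz[1:2]), fs / n, tolerance = 1e-12)  # 0.0033 Hz, 0.2 bpm
  bf <- breathing_frequency(sp)
  expect_identical(bf$bin, 75L)
  expect_equal(bf$freq_hz, 0.25)
  expect_equal(bf$freq_bpm, 15)

  # dominant out-of-band tone must not win
  y2 <- 5 * sin(2 * pi * 2 * t) + sin(2 * pi * 0.3 * t)
  bf2 <- breathing_frequency(dft_spectrum(y2, fs = fs))
  expect_equal(bf2$freq_hz, 0.3, tolerance = 1e-9)

  expect_error(breathing_frequency(sp, 5.5, 6), "band")  # beyond Nyquist
})

test_that("windowed features report per-window means and step with the breathing rate", {
  const <- breath_signal(rep(27, 3000), fs = 10)
  wf <- windowed_features(const)
  expect_identical(nrow(wf), 5L)
  expect_true(all(wf$mean_value == 27))

  # rate steps 15 -> 20 bpm at mid-record; 60 s windows resolve 1 bpm
  fs <- 10; n <- 3000
  t <- (0:(n - 1)) / fs
  x <- ifelse(t < 150, sin(2 * pi * 0.25 * t), sin(2 * pi * (1 / 3) * t))
  wf2 <- windowed_features(breath_signal(27 + x, fs), 60)
  expect_true(all(abs(wf2$freq_bpm[1:2] - 15) <= 1))
  expect_true(all(abs(wf2$freq_bpm[4:5] - 20) <= 1))

  expect_error(windowed_features(breath_signal(rep(1, 50), 10), 60), "one window")
})

test_that("recovery regression recovers exact and noisy slopes", {
  t_c <- seq(30, 390, by = 60)                    # 7 windows over ~7 min
  mk <- function(y) {
    structure(tibble::tibble(window = seq_along(t_c), t_center = t_c,
                             mean_value = y, freq_hz = 0.25, freq_bpm = y),
              class = c("windowed_features", class(tibble::tibble())))
  }
  fitT <- recovery_regression(mk(30 - 0.16 * t_c / 60), c(0, 420), "mean_value")
  expect_equal(fitT$slope_per_min, -0.16, tolerance = 1e-10)
  expect_lte(fitT$S_percent, 1e-16)
  fitF <- recovery_regression(mk(20 - 0.72 * t_c / 60), c(0, 420), "freq_bpm")
  expect_equal(fitF$slope_per_min, -0.72, tolerance = 1e-10)

  # exact fit makes summary.lm warn about perfect residuals; that is expected
  td <- suppressWarnings(tidy(fitT))
  expect_identical(td$term, c("(Intercept)", "t_min"))
  expect_equal(suppressWarnings(glance(fitT))$slope_per_min, fitT$slope_per_min)

  # noisy replicates: mean estimated slope within 5% of truth
  set.seed(99)
  slopes <- replicate(200, {
    y <- 20 - 0.72 * t_c / 60 + rnorm(length(t_c), sd = 0.5)
    recovery_regression(mk(y), c(0, 420), "freq_bpm")$slope_per_min
  })
  expect_lte(abs(mean(slopes) - (-0.72)), 0.05 * 0.72)

  expect_error(recovery_regression(mk(rep(1, 7)), c(0, 65)), "at least 3")
})

test_that("response delays are recovered for steps, censored when flat, and ~0.693 tau for exponentials", {
  sched <- activity_schedule(c(0, 600, 1200, 1800), c(600, 1200, 1800, 2400),
                             c("load", "rest", "load", "rest"))
  t_c <- seq(30, 2370, by = 60)
  mk <- function(y) {
    structure(tibble::tibble(window = seq_along(t_c), t_center = t_c,
                             mean_value = y, freq_hz = y / 60, freq_bpm = y),
              class = c("windowed_features", class(tibble::tibble())))
  }
  # underlying signal steps exactly 90 s after each boundary; window means
  # of the continuous step (the mid-step window holds the half-mixed value)
  g <- function(t) ifelse(t < 690, 20, ifelse(t < 1290, 15, ifelse(t < 1890, 20, 15)))
  step_y <- vapply(t_c, function(tc) mean(g(seq(tc - 29.5, tc + 29.5, by = 1))),
                   numeric(1))
  d <- response_delay(mk(step_y), sched)
  expect_equal(d$delay_s, rep(90, 3), tolerance = 1e-9)
  expect_false(any(d$censored))

  flat <- response_delay(mk(rep(17, length(t_c))), sched)
  expect_true(all(flat$censored))
  expect_equal(flat$delay_s, rep(600, 3))

  # exponential approach with time constant tau after the first boundary
  tau <- 120
  y <- ifelse(t_c < 600, 20, 20 - 5 * (1 - exp(-(t_c - 600) / tau)))
  d2 <- response_delay(mk(y), sched)
  expect_lte(abs(d2$delay_s[1] - 0.693 * tau), 60)

  expect_error(activity_schedule(c(0, 500), c(600, 1100), c("load", "rest")),
               "contiguous")
  expect_error(activity_schedule(0, 600, "warmup"), "load")
  expect_error(response_delay(mk(step_y), sched, crossing = 1.2), "crossing")
})
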