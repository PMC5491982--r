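# frames with oscillating rectangular patches on a flat background
patch_frames <- function(n_frames, shape, patches, amp = 1, base = 27) {
  lapply(seq_len(n_frames), function(i) {
    f <- matrix(base, shape[1], shape[2])
    for (p in patches) {
      f[(p$r0 + 1):p$r1, (p$c0 + 1):p$c1] <- base + amp * sin(2 * pi * (i - 1) / 8)
    }
    f
  })
}

test_that("change_map equals the per-pixel peak-to-peak oracle", {
  frames <- lapply(1:7, function(i) matrix(rnorm(12 * 9), 12, 9))
  cm <- change_map(frames, smoothing_radius = 0)
  oracle <- matrix(0, 12, 9)
  for (r in 1:12) for (c in 1:9) {
    v <- vapply(frames, function(f) f[r, c], numeric(1))
    oracle[r, c] <- max(v) - min(v)
  }
  expect_equal(cm, oracle, tolerance = 1e-12)
  expect_true(all(cm >= 0))

  same <- replicate(3, matrix(5, 4, 4), simplify = FALSE)
  expect_true(all(change_map(same) == 0))

  alt <- list(matrix(26, 5, 5), matrix(26, 5, 5))
  alt[[2]][3, 3] <- 28
  cm2 <- change_map(alt, smoothing_radius = 0)
  expect_identical(cm2[3, 3], 2)
  expect_identical(sum(cm2), 2)

  expect_error(change_map(same[1]), "two frames")
  expect_error(change_map(list(matrix(0, 2, 2), matrix(0, 3, 3))), "shape")
})

test_that("box smoothing matches a brute-force windowed mean with border renormalisation", {
  m <- matrix(rnorm(48), 6, 8)
  sm <- breathcam:::box_smooth(m, 1L)
  oracle <- matrix(0, 6, 8)
  for (r in 1:6) for (c in 1:8) {
    rr <- max(1, r - 1):min(6, r + 1)
    cc <- max(1, c - 1):min(8, c + 1)
    oracle[r, c] <- mean(m[rr, cc])
  }
  expect_equal(sm, oracle, tolerance = 1e-12)
})

test_that("component labelling is 8-connected", {
  mask <- matrix(FALSE, 6, 6)
  mask[1, 1] <- TRUE; mask[2, 2] <- TRUE; mask[3, 3] <- TRUE   # one diagonal chain
  mask[6, 1] <- TRUE; mask[5, 6] <- TRUE                       # two isolated pixels
  comps <- breathcam:::label_components(mask)
  areas <- sort(vapply(comps, function(x) x$area, numeric(1)))
  expect_identical(areas, c(1, 1, 3))
})

test_that("initial detection finds the oscillating patch and rejects static scenes", {
  true_roi <- roi(20, 30, 30, 44)
  frames <- patch_frames(20, c(42, 80), list(true_roi))
  det <- detect_initial_roi(frames, roi_track_params(smoothing_radius = 0))
  expect_gte(roi_iou(det, true_roi), 0.5)

  static <- replicate(20, matrix(27, 42, 80), simplify = FALSE)
  expect_error(detect_initial_roi(static), class = "breathcam_detection_error")
})

test_that("with two oscillating patches the larger one wins the initial detection", {
  big <- roi(10, 10, 22, 24)
  small <- roi(40, 70, 48, 78)
  frames <- patch_frames(20, c(60, 100), list(big, small))
  det <- detect_initial_roi(frames, roi_track_params(smoothing_radius = 0))
  expect_identical(unclass(det)[c("r0", "c0", "r1", "c1")],
                   unclass(big)[c("r0", "c0", "r1", "c1")])
})

test_that("update_roi falls back to the previous ROI on static windows", {
  prev <- roi(5, 5, 10, 10)
  static <- replicate(10, matrix(27, 42, 80), simplify = FALSE)
  upd <- update_roi(prev, static)
  expect_true(attr(upd, "fallback"))
  expect_identical(unclass(upd)[c("r0", "c0", "r1", "c1")],
                   unclass(prev)[c("r0", "c0", "r1", "c1")])
})

test_that("tracking a noise-free static mouth keeps the ROI centre within 1 px", {
  p <- scene_params(duration = 12, seed = 8, noise_std = 0, include_bar = FALSE,
                    frame_shape = c(42L, 80L))
  sc <- simulate_thermal_sequence(p)
  tr <- track_mouth_roi(scene_temps(sc), fs = 10)
  ctr <- cbind((tr$r0 + tr$r1) / 2, (tr$c0 + tr$c1) / 2)
  drift <- sqrt((ctr[, 1] - ctr[1, 1])^2 + (ctr[, 2] - ctr[1, 2])^2)
  expect_lte(max(drift), 1)
  expect_false(any(tr$fallback))
})

test_that("the tracker trace agrees with frame-by-frame update_roi", {
  p <- scene_params(duration = 6, seed = 12, include_bar = FALSE,
                    frame_shape = c(42L, 80L))
  temps <- scene_temps(simulate_thermal_sequence(p))
  params <- roi_track_params(history_sec = 1.5)
  tr <- track_mouth_roi(temps, fs = 10, params)
  h <- 15L
  prev <- detect_initial_roi(temps[1:h], params)
  for (i in (h + 1):length(temps)) {
    prev <- update_roi(prev, temps[(i - h + 1):i], params)
    expect_identical(c(tr$r0[i], tr$c0[i], tr$r1[i], tr$c1[i]),
                     c(prev$r0, prev$c0, prev$r1, prev$c1))
  }
})

test_that("the moving ROI follows head drift better than the fixed ROI and sees a wider range", {
  sc <- simulate_thermal_sequence(drift_scene(seed = 4))
  temps <- scene_temps(sc)
  tr <- track_mouth_roi(temps, fs = 10, drift_track_params())
  iou_moving <- mean_trace_iou(tr, sc$truth$mouth_roi)
  fixed <- trace_rois(tr)[[1]]
  iou_fixed_end <- roi_iou(fixed, sc$truth$mouth_roi[[length(temps)]])
  expect_gte(iou_moving, 0.5)
  expect_gt(iou_moving, iou_fixed_end)
  fixed_series <- vapply(temps, mean_temperature, numeric(1), roi = fixed)
  expect_gte(diff(range(tr$mean_temp)), diff(range(fixed_series)))
})

test_that("mean_temperature and range_fraction match brute-force oracles", {
  f <- matrix(c(26, 27, 28, 29), 2, 2)
  r <- roi(0, 0, 2, 2)
  expect_identical(mean_temperature(f, r), 27.5)
  expect_identical(mean_temperature(matrix(26.5, 5, 5), roi(1, 1, 4, 4)), 26.5)

  set.seed(33)
  big <- matrix(rnorm(30 * 20, mean = 27), 30, 20)
  rr <- roi(3, 2, 25, 17)
  sub <- big[4:25, 3:17]
  expect_equal(mean_temperature(big, rr), sum(sub) / length(sub), tolerance = 1e-12)
  expect_equal(range_fraction(big, rr, 26.5, 27.5),
               100 * sum(sub >= 26.5 & sub <= 27.5) / length(sub), tolerance = 1e-12)

  expect_identical(range_fraction(matrix(27, 4, 4), roi(0, 0, 4, 4), 26, 28), 100)
  expect_identical(range_fraction(matrix(31, 4, 4), roi(0, 0, 4, 4), 26, 28), 0)
  expect_error(range_fraction(big, rr, 28, 26), "t_low")
  expect_error(mean_temperature(big, roi(0, 0, 40, 10)), "outside")
})

test_that("flat-field statistics recover a known noise level", {
  expect_identical(flat_field_stats(matrix(27, 10, 10))$sd, 0)
  withr::with_seed(21, {
    ff <- matrix(27 + rnorm(1e4, sd = 0.1), 100, 100)
  })
  st <- flat_field_stats(ff)
  expect_gte(st$sd, 0.09)
  expect_lte(st$sd, 0.11)
  expect_equal(st$mean, mean(ff), tolerance = 1e-12)
  m <- matrix(27, 5, 5); m[3, 3] <- 40
  expect_equal(flat_field_stats(m)$mean, (24 * 27 + 40) / 25, tolerance = 1e-12)
})

test_that("range_fraction stays precise over a 2-minute stationary sequence sampled every 5 s", {
  p <- scene_params(duration = 120, fs = 0.2, breath_freq = 0.08, seed = 14,
                    include_bar = FALSE, frame_shape = c(42L, 80L))
  temps <- scene_temps(simulate_thermal_sequence(p))
  expect_length(temps, 24)
  eye_region <- roi(2, 20, 20, 60)  # static facial area away from the mouth
  fr <- vapply(temps, range_fraction, numeric(1), roi = eye_region,
               t_low = 26, t_high = 28)
  cv <- stats::sd(fr) / mean(fr)
  expect_lte(cv, 0.07)
})
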