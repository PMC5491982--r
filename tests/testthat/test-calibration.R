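test_that("grey-to-temperature is the exact affine map", {
  sc <- temperature_scale(20, 30)
  expect_identical(grey_to_temperature(matrix(0, 1, 1), sc)[1, 1], 20)
  expect_identical(grey_to_temperature(matrix(255, 1, 1), sc)[1, 1], 30)
  expect_equal(grey_to_temperature(matrix(128, 1, 1), sc)[1, 1],
               20 + 128 * 10 / 255, tolerance = 1e-12)
  # affine: differences proportional to grey differences, any scale
  g <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  t1 <- grey_to_temperature(g, temperature_scale(-40, 330))
  expect_equal(t1, -40 + g * 370 / 255, tolerance = 1e-12)
  expect_error(grey_to_temperature(matrix(300, 1, 1), sc), "0..255")
  expect_error(temperature_scale(25, 25))
})

test_that("a zero-jitter training set is memorised perfectly and degenerate labels error", {
  tz <- make_digit_training_set(4, jitter = jitter_params(0, c(1, 1), 0), seed = 1)
  m <- train_digit_classifier(tz$glyphs, tz$labels, epochs = 400, lr = 2, seed = 3)
  hz <- make_digit_training_set(2, jitter = jitter_params(0, c(1, 1), 0), seed = 9)
  expect_identical(classifier_accuracy(m, hz$glyphs, hz$labels), 1)
  expect_error(train_digit_classifier(tz$glyphs[1:4], rep("7", 4)), "two")
})

test_that("classification is a proper softmax with deterministic training", {
  m <- cached_classifier()
  g7 <- matrix(breathcam:::render_glyph_cell("7", c(11L, 6L)), 11, 6)
  res <- classify_glyph(m, g7)
  expect_identical(res$label, "7")
  expect_equal(sum(res$probs), 1, tolerance = 1e-9)
  expect_true(all(res$probs >= 0))
  # a uniform blank cell is recognised as the blank sign-cell state, never a digit
  blank <- classify_glyph(m, matrix(40, 11, 6))
  expect_identical(blank$label, " ")
  # seeded retraining reproduces identical weights
  ts <- make_digit_training_set(5, seed = 2)
  m1 <- train_digit_classifier(ts$glyphs, ts$labels, epochs = 50, seed = 4)
  m2 <- train_digit_classifier(ts$glyphs, ts$labels, epochs = 50, seed = 4)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$W2, m2$W2)
})

test_that("calibration bars round-trip exactly at the printed precision", {
  m <- cached_classifier()
  lay <- bar_layout(c(56, 80))
  cases <- list(c(-40, 330), c(22.4, 31.7), c(26, 28), c(-0.5, 2),
                c(19.9, 20.1), c(-12.3, 104.8))
  for (v in cases) {
    frame <- rbind(render_calibration_bar(v[1], v[2], lay), matrix(0L, 42, 80))
    sc <- read_calibration_bar(frame, lay, m)
    expect_identical(c(sc$tmin, sc$tmax), v)
  }
})

test_that("corrupted or inconsistent bars raise calibration errors with the frame index", {
  m <- cached_classifier()
  lay <- bar_layout(c(56, 80))
  frame <- rbind(render_calibration_bar(22.4, 31.7, lay), matrix(0L, 42, 80))
  # blank out one digit cell
  b <- lay$min_cells[[3]]
  bad <- frame
  bad[(b$r0 + 1):b$r1, (b$c0 + 1):b$c1] <- 40L
  err <- tryCatch(read_calibration_bar(bad, lay, m, frame_index = 17L),
                  breathcam_calibration_error = function(e) e)
  expect_s3_class(err, "breathcam_calibration_error")
  expect_match(conditionMessage(err), "17")
  # swap the min and max fields so the read range is inverted
  swapped <- frame
  for (i in seq_along(lay$min_cells)) {
    a <- lay$min_cells[[i]]; z <- lay$max_cells[[i]]
    swapped[(a$r0 + 1):a$r1, (a$c0 + 1):a$c1] <- frame[(z$r0 + 1):z$r1, (z$c0 + 1):z$c1]
    swapped[(z$r0 + 1):z$r1, (z$c0 + 1):z$c1] <- frame[(a$r0 + 1):a$r1, (a$c0 + 1):a$c1]
  }
  expect_error(read_calibration_bar(swapped, lay, m), class = "breathcam_calibration_error")
  # layout outside the frame
  expect_error(read_calibration_bar(frame[1:10, ], lay, m), "outside")
})

test_that("the full render-read-map loop reproduces temperatures within quantization", {
  m <- cached_classifier()
  p <- scene_params(duration = 2, seed = 6)
  sc <- simulate_thermal_sequence(p)
  cal <- calibrate_frames(sc$frames, sc$layout, m)
  expect_equal(cal$scales$tmin, sc$truth$tmin)
  expect_equal(cal$scales$tmax, sc$truth$tmax)
  ref <- scene_temps(sc)
  for (i in seq_along(ref)) {
    expect_equal(cal$temps[[i]], ref[[i]], tolerance = 1e-12)
  }
})

test_that("classifiers survive a JSON save/load round trip", {
  m <- cached_classifier()
  path <- withr::local_tempfile(fileext = ".json")
  save_classifier(m, path)
  m2 <- load_classifier(path)
  ho <- make_digit_training_set(5, seed = 31, chars = c(bar_charset(), " "))
  p1 <- breathcam:::classify_glyphs(m, ho$glyphs)
  p2 <- breathcam:::classify_glyphs(m2, ho$glyphs)
  expect_identical(p1$label, p2$label)
  expect_equal(p1$confidence, p2$confidence, tolerance = 1e-12)
})
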