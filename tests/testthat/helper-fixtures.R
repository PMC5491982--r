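# Shared fixtures. The bar-reader network is trained once per session and
# reused; tests that need specific training regimes train their own.

cached_classifier <- local({
  model <- NULL
  function() {
    if (is.null(model)) {
      model <<- default_bar_classifier(n_per_class = 60, epochs = 800, seed = 7)
    }
    model
  }
})

# temperature frames of a synthetic thermal scene, calibrated from the
# ground-truth per-frame spans (bypasses OCR; OCR has its own tests)
scene_temps <- function(scene) {
  img_box <- if (is.null(scene$layout)) NULL else scene$layout$image_box
  lapply(seq_along(scene$frames), function(i) {
    g <- scene$frames[[i]]
    if (!is.null(img_box)) g <- g[(img_box$r0 + 1):img_box$r1, , drop = FALSE]
    grey_to_temperature(g, temperature_scale(scene$truth$tmin[i], scene$truth$tmax[i]))
  })
}

trace_rois <- function(trace) {
  lapply(seq_len(nrow(trace)), function(i) {
    roi(trace$r0[i], trace$c0[i], trace$r1[i], trace$c1[i])
  })
}

mean_trace_iou <- function(trace, true_rois) {
  mean(vapply(seq_len(nrow(trace)), function(i) {
    roi_iou(trace_rois(trace)[[i]], true_rois[[i]])
  }, numeric(1)))
}

# the head-drift fixture: 2 s stationary lead-in, then 1 px/frame lateral
# drift across a wide frame
drift_scene <- function(seed = 4, duration = 12) {
  n <- duration * 10
  scene_params(frame_shape = c(42L, 160L), duration = duration, seed = seed,
               include_bar = FALSE,
               mouth_center_path = mouth_path_linear(c(29, 25), c(0, 1), n,
                                                     hold_frames = 20))
}

# tracker configuration for fast head motion: shortest usable history and no
# change-map smoothing, so the bounding box hugs the currently moving patch
drift_track_params <- function() {
  roi_track_params(history_sec = 1, smoothing_radius = 0)
}
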