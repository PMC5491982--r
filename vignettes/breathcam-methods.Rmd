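---
title: "Contactless breathing analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contactless breathing analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathcam)
```

## The measurement problem

Breathing modulates two quantities that can be observed without touching the
subject. Exhaled air periodically warms (and inhalation cools) the skin around
the mouth and nostrils, which a low-cost long-wave infrared camera sees as a
periodic change of the mean temperature in a small facial region. The chest
wall moves towards and away from a depth (time-of-flight) camera, which sees a
periodic change of the mean distance in a chest region. Both records are
ordinary scalar time series `x(n)`, `n = 0..N-1`, sampled at a frame rate
`fs`, and both carry the same fundamental frequency: the breathing rate.

`breathcam` implements the full chain for both modalities:

1. **Adaptive thermal calibration.** Consumer thermal cameras export 8-bit
   grey frames whose grey-to-temperature mapping changes every frame; the
   frame's actual span is printed in an overlay calibration bar. A shallow
   neural network reads the printed minimum and maximum and the affine map
   `T = tmin + g (tmax - tmin)/255` converts grey levels to degrees Celsius.
2. **Adaptive mouth-ROI tracking.** The breathing region is found as the area
   with the largest temperature changes over a short trailing history and is
   re-detected each frame, following slow head movement.
3. **Series extraction.** Mean ROI temperature per frame (thermal), mean ROI
   distance per frame (depth).
4. **Spectral and windowed analysis.** FIR band-pass filtering, DFT,
   in-band peak picking; per-window means and rates; recovery regressions
   after exercise; response delays around activity changes.

A synthetic scene generator produces paired thermal/depth recordings with
known ground truth, so every stage is testable end to end without recorded
human data.

## Calibration-bar recognition

The bar prints two fixed-width temperature fields (one decimal place, a sign
cell that is blank for positive values) in a 5x7 raster font, plus a full
0-255 grey gradient strip. The recogniser is a two-layer network: a sigmoidal
hidden layer (32 units by default) and a softmax output layer over 13 classes
-- the digits, the decimal point, the minus sign, and the blank cell state.
Training is plain full-batch gradient descent on the cross-entropy loss
(default 2000 epochs, learning rate 2 applied to the mean gradient, seeded
initialisation), on glyphs rendered by the same renderer with randomised
shift, scale and grey-noise jitter.

Three normalisation choices matter and were settled by measurement:

* **Fixed 8-bit input scale.** Cells are mapped to `[0, 1]` by `g / 255`
  rather than per-cell contrast stretching. Overlay text has globally stable
  ink and background levels; per-cell stretching amplifies pixel noise in
  blank cells to full range and makes the blank state unlearnable.
* **No hard binarisation.** Thresholding (e.g. Otsu) deletes the
  partial-intensity pixels that anti-aliased scaling produces; with it,
  held-out accuracy plateaus near 0.97 regardless of capacity. Keeping grey
  values lifts it above 0.995.
* **An explicit blank class.** Fields are fixed width, so a blank sign cell
  is a legitimate state the reader must recognise, not an error. Genuinely
  corrupted cells are still rejected by a softmax-confidence threshold
  (default 0.5), and a blank inside a numeric field is a calibration error
  carrying the frame index.

The default jitter scales glyphs by 0.95-1.1. The font is already at its
minimum legible raster size; scaling a 7-row glyph down to 6 rows removes
whole strokes and produces characters no reader could classify, which is not
a property of any real overlay.

## Mouth-ROI detection and tracking

The change map of a frame window is the per-pixel peak-to-peak temperature
(max minus min), optionally box-smoothed. It is thresholded at a high
quantile (default 0.95) and 8-connected components within configurable area
bounds (default at least 9 px) are extracted; the initial detection takes the
largest component's bounding box, and each per-frame update takes the
qualifying component whose centroid is nearest the previous ROI's centre
(ties: larger area, then lower corner). When nothing qualifies -- a static
window, or a noise-only threshold exceedance fragmenting below the area bound
-- the previous ROI is kept and the frame is flagged, keeping the series
gap-free.

The history window defaults to 2 s. The usable range is 1-8 s: the window
must span an appreciable part of a breath cycle so the oscillation dominates
the map (any half cycle of a sinusoid has peak-to-peak of at least one
amplitude), but everything the head sweeps during the window is smeared into
the detected component. At the extreme of ~1 px/frame head motion the right
operating point is the short end -- 1 s history and no smoothing, since the
box filter additionally inflates the bounding box by its radius; that
configuration holds the mean intersection-over-union with the true mouth
patch near 0.6 on drift fixtures while the default settings suit
near-stationary subjects. Coordinates are 0-based, half-open, row-major with
the origin at the top-left pixel; ROI tables on disk use the same convention.

## Breathing-rate estimation

De-noising uses a linear-phase FIR band-pass, designed by the windowed-sinc
(Hamming) method for the breathing band 0.05-1.5 Hz. The default length is
M = 512 taps at fs = 10 Hz: the lower edge sits close to DC, and the Hamming
transition width (about `3.3 fs / M` = 0.064 Hz) must fit between 0 and
0.05 Hz for meaningful DC rejection. Every design is verified against its
realised response (at least -6 dB across `[2 f_low, 0.8 f_high]`, at most
-20 dB at DC and Nyquist) and fails loudly otherwise. Filtering is the
causal convolution with zero initial conditions; output length equals input
length.

The rate estimate is the largest DFT magnitude over bins whose frequency
`f_k = (k/N) fs` lies in the band, with ties resolved to the lowest bin and
no peak interpolation: estimates are reported at the record's resolution
`fs / N` (0.0033 Hz = 0.2 bpm for a 300 s record at 10 Hz), which is how the
method's agreement between modalities is defined. The record mean is removed
before filtering, so the whole-record estimator is insensitive to the
filter's residual DC leakage.

Windowed features use non-overlapping 60 s windows by default: the raw
window mean, and the rate of the mean-removed, band-passed window. The
per-window filter defaults to `min(512, window/2)` taps so the startup
transient stays inside the window; its response verification is skipped
because the window mean is removed first, making strict DC suppression
non-load-bearing for short windows.

**Recovery regression.** An OLS fit of a windowed feature against time (in
minutes) over a post-exercise interval. Alongside the slope we report
`S = 100 * mean(residual^2) / mean(fitted)^2` -- a mean squared error as a
percentage of the squared mean fitted level. This normalisation is this
package's own definition, chosen so S is scale-free and exactly zero for a
noiseless linear decay.

**Response delay.** Delay definitions around activity changes are not
standardised; ours is a crossing-fraction rule. At each boundary between
schedule segments, baseline = mean of the last two windows before the
boundary, steady = mean of the last two windows of the new segment, and the
delay is the time until the feature first reaches
`baseline + crossing (steady - baseline)` (default crossing 0.5), linearly
interpolated between window centres. A feature that never reaches the level
is censored at the segment length. With 60 s windows a step in the
underlying signal 90 s after the boundary is recovered exactly, because the
window containing the step holds the half-mixed mean; an exponential
approach with time constant tau crosses at `0.693 tau` within one window
spacing.

## What the synthetic scenes emulate

A thermal scene is a static smooth face field (a warm Gaussian blob on a
cooler background) with a rectangular mouth patch whose temperature is
`base + drift t + A sin(2 pi f t)`, i.i.d. Gaussian pixel noise, per-frame
rendering to 8-bit grey over the frame's own span rounded outwards to
0.1 degC, and the calibration bar printing that span. A depth scene is a
body blob in front of a background plane with a chest patch at
`d0 + a sin(2 pi f t)` plus noise, clamped to the 0.4-4 m sensor range.

Defaults are the study conditions used throughout the tests: 10 Hz sampling,
300 s records (N = 3000), breathing at 0.05-1.5 Hz, mouth base temperature
27 degC with 1 degC amplitude, 0.1 degC thermal pixel noise (matching a
flat-field noise floor of a consumer microbolometer), chest at 1.5 m with
5 mm amplitude and 3 mm depth noise. Head motion is modelled as linear or
sinusoidal drift of the mouth-centre path at up to 1 px/frame. Thermal
frames default to 56 x 80 px (a scaled-down sensor raster that keeps test
suites fast; the geometry, not the pixel count, carries the method), and the
drift fixtures use 42 x 160 px so a 1 px/frame walk fits in frame.

The generator deliberately omits: radiometric sensor physics, lens effects
and vignetting, facial structure and expression changes, correlated or
fixed-pattern sensor noise, vendor overlay fonts, and depth shadows/missing
returns (invalid depth pixels are supported in extraction but not
synthesised by default). Passing tests therefore demonstrate the internal
correctness and statistical behaviour of the chain under the stated model --
exact calibration round trips, sub-bin rate recovery, tracker IoU -- not
performance on any specific real camera.

## Numerical details worth knowing

* Grey encoding uses the printed (rounded-out) span, so decoding is exact up
  to one quantisation step `(tmax - tmin)/255` per pixel; a degenerate span
  is widened to 0.1 degC before printing and rejected by the bar renderer's
  validation (`tmin < tmax`, within -40..330 degC).
* All stochastic stages (scene noise, jitter, weight initialisation) are
  seeded and bit-reproducible; the pipeline writes byte-identical reports
  for identical configuration and seed.
* Long traces use a block prefix/suffix decomposition for the sliding
  min/max (exactly equal to the direct per-window computation, verified in
  tests), so tracking 3000 frames costs seconds, not minutes.
* Ties: spectral peaks resolve to the lowest bin; component selection to
  the nearest centroid, then larger area, then lower corner; `which.max`
  semantics are never relied on implicitly.

## Limitations

OCR is trained on this package's renderer; reading a specific vendor's
overlay requires a user-supplied layout and retraining on that font. The
depth chest ROI is fixed (user-configured), as adaptivity is only defined
for the thermal mouth region. Delay and S definitions are this package's
operationalisations and should be cited as such. The tracker assumes the
breathing region is the dominant source of temperature change; strong
non-breathing motion (talking, wind) violates the model.
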