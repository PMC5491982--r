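# Glyph normalization: map the 8-bit cell onto [0, 1] and resize to the
# classifier input shape. Overlay text has globally stable ink/background
# grey levels, so the fixed scale is kept rather than per-cell contrast
# stretching (which would blow pixel noise in blank cells up to full range);
# anti-aliased strokes keep their partial intensities.
normalize_glyph <- function(cell, input_shape) {
  if (!is.matrix(cell) || any(dim(cell) < 2)) abort("glyph must be a numeric matrix")
  resize_bilinear(pmin(1, pmax(0, cell / 255)), input_shape)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

nn_forward <- function(model, X) {
  H <- 1 / (1 + exp(-(model$W1 %*% X + as.numeric(model$b1))))
  softmax_cols(model$W2 %*% H + as.numeric(model$b2))
}

#' Train the calibration-bar digit classifier
#'
#' A two-layer neural network: a sigmoidal hidden layer and a softmax output
#' layer, trained by plain batch gradient descent on the cross-entropy loss.
#' It recognises the individual characters printed in the thermal frames'
#' calibration bar (digits, decimal point, minus sign).
#'
#' @param glyphs List of grey glyph matrices (e.g. from
#'   [make_digit_training_set()]).
#' @param labels Character labels, one per glyph; at least two classes.
#' @param hidden_units Hidden-layer width.
#' @param epochs Gradient-descent iterations over the full batch.
#' @param lr Learning rate (applied to the mean gradient).
#' @param seed Seed for the weight initialisation.
#' @param input_shape Glyph shape fed to the network; defaults to the shape
#'   of the first glyph.
#' @return A `"digit_classifier"` with weights, class labels and the final
#'   training loss.
#' @export
train_digit_classifier <- function(glyphs, labels, hidden_units = 32L,
                                   epochs = 2000L, lr = 2, seed = 1L,
                                   input_shape = NULL) {
  stopifnot(length(glyphs) == length(labels), length(glyphs) > 0)
  classes <- sort(unique(as.character(labels)), method = "radix")
  if (length(classes) < 2) abort("need at least two character classes to train")
  input_shape <- input_shape %||% dim(glyphs[[1]])
  d <- prod(input_shape)
  X <- vapply(glyphs, function(g) as.numeric(normalize_glyph(g, input_shape)),
              numeric(d))
  y <- match(as.character(labels), classes)
  n <- ncol(X)
  Tg <- matrix(0, length(classes), n)
  Tg[cbind(y, seq_len(n))] <- 1

  h <- as.integer(hidden_units)
  model <- withr::with_seed(as.integer(seed), list(
    W1 = matrix(rnorm(h * d, sd = 1 / sqrt(d)), h, d),
    b1 = matrix(0, h, 1),
    W2 = matrix(rnorm(length(classes) * h, sd = 1 / sqrt(h)), length(classes), h),
    b2 = matrix(0, length(classes), 1)
  ))
  loss <- NA_real_
  for (e in seq_len(epochs)) {
    A1 <- model$W1 %*% X + matrix(model$b1, h, n)
    H <- 1 / (1 + exp(-A1))
    P <- softmax_cols(model$W2 %*% H + matrix(model$b2, nrow(Tg), n))
    loss <- -mean(log(pmax(P[Tg == 1], 1e-300)))
    if (!is.finite(loss)) abort("training failure: non-finite loss")
    dZ <- (P - Tg) / n
    dW2 <- dZ %*% t(H)
    db2 <- rowSums(dZ)
    dA1 <- (t(model$W2) %*% dZ) * H * (1 - H)
    dW1 <- dA1 %*% t(X)
    db1 <- rowSums(dA1)
    model$W2 <- model$W2 - lr * dW2
    model$b2 <- model$b2 - lr * db2
    model$W1 <- model$W1 - lr * dW1
    model$b1 <- model$b1 - lr * db1
  }
  structure(
    list(W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
         classes = classes, input_shape = as.integer(input_shape),
         hidden_units = h, final_loss = loss),
    class = "digit_classifier"
  )
}

#' @export
print.digit_classifier <- function(x, ...) {
  cat(sprintf("<digit_classifier> %d classes, %d inputs, %d hidden units, final loss %.4g\n",
              length(x$classes), prod(x$input_shape), x$hidden_units, x$final_loss))
  invisible(x)
}

# batch forward pass over a list of raw glyph cells; plain list output, this
# sits on the per-frame hot path
classify_glyphs <- function(model, glyphs) {
  d <- prod(model$input_shape)
  X <- vapply(glyphs, function(g) {
    as.numeric(normalize_glyph(g, model$input_shape))
  }, numeric(d))
  X <- matrix(X, nrow = d)
  P <- nn_forward(model, X)
  k <- max.col(t(P), ties.method = "first")
  list(label = model$classes[k],
       confidence = P[cbind(k, seq_len(ncol(P)))])
}

#' Classify a single glyph
#'
#' Normalizes the cell (Otsu binarization, resize to the model input shape)
#' and returns the softmax argmax with its probability. Ties break towards
#' the lowest class index. Callers implement rejection by thresholding
#' `confidence` (the bar reader uses 0.5).
#'
#' @param model A [train_digit_classifier()] fit.
#' @param glyph Grey matrix of one character cell.
#' @return List with `label`, `confidence`, and the full named `probs` vector.
#' @export
classify_glyph <- function(model, glyph) {
  stopifnot(inherits(model, "digit_classifier"))
  x <- as.numeric(normalize_glyph(glyph, model$input_shape))
  if (length(x) != prod(model$input_shape)) abort("glyph shape mismatch")
  P <- nn_forward(model, matrix(x, ncol = 1))[, 1]
  k <- which.max(P)
  list(label = model$classes[k], confidence = unname(P[k]),
       probs = stats::setNames(P, model$classes))
}

#' Held-out accuracy of a digit classifier
#'
#' @param model A `"digit_classifier"`.
#' @param glyphs,labels Evaluation glyphs and their true labels.
#' @return Fraction correctly classified.
#' @export
classifier_accuracy <- function(model, glyphs, labels) {
  pred <- classify_glyphs(model, glyphs)
  mean(pred$label == as.character(labels))
}

#' Save / load a digit classifier as JSON
#'
#' @param model A `"digit_classifier"`.
#' @param path File path.
#' @export
save_classifier <- function(model, path) {
  out <- list(classes = model$classes, input_shape = model$input_shape,
              hidden_units = model$hidden_units, final_loss = model$final_loss,
              W1 = model$W1, b1 = as.numeric(model$b1),
              W2 = model$W2, b2 = as.numeric(model$b2))
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(W1 = as.matrix(x$W1), b1 = matrix(x$b1, ncol = 1),
         W2 = as.matrix(x$W2), b2 = matrix(x$b2, ncol = 1),
         classes = x$classes, input_shape = x$input_shape,
         hidden_units = x$hidden_units, final_loss = x$final_loss),
    class = "digit_classifier"
  )
}
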