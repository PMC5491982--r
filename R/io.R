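#' Write / read thermal frames as numbered 8-bit PNG files
#'
#' Frames are written as `frame_000000.png`, `frame_000001.png`, ... in
#' acquisition order.
#'
#' @param frames List of integer grey matrices (0-255).
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_thermal_frames <- function(frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(frames)) {
    png::writePNG(frames[[i]] / 255,
                  file.path(dir, sprintf("frame_%06d.png", i - 1L)))
  }
  invisible(dir)
}

#' @rdname write_thermal_frames
#' @export
read_thermal_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) abort(paste0("no PNG frames in ", dir))
  lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img <- img[, , 1]
    matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  })
}

#' Write / read depth frames as CSV matrices
#'
#' One plain-text CSV matrix of distances (metres) per frame,
#' `frame_000000.csv`, ...
#'
#' @param frames List of numeric depth matrices.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_depth_frames <- function(frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(frames)) {
    utils::write.table(frames[[i]],
                       file.path(dir, sprintf("frame_%06d.csv", i - 1L)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_depth_frames
#' @export
read_depth_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0) abort(paste0("no CSV frames in ", dir))
  lapply(files, function(f) {
    as.matrix(utils::read.table(f, sep = ",", header = FALSE))
  })
}

# ground truth of a synthetic scene as JSON (plain lists; roi as 4 ints)
write_ground_truth <- function(truth, path) {
  enc <- truth
  if (!is.null(enc$mouth_roi)) {
    enc$mouth_roi <- lapply(enc$mouth_roi, function(r) unlist(r[c("r0", "c0", "r1", "c1")]))
  }
  if (!is.null(enc$chest_roi)) {
    enc$chest_roi <- unlist(enc$chest_roi[c("r0", "c0", "r1", "c1")])
  }
  jsonlite::write_json(enc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
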