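#' Rectangular region of interest
#'
#' An axis-aligned rectangle in image coordinates. Coordinates are 0-based and
#' half-open: the region covers pixel rows `[r0, r1)` and columns `[c0, c1)`
#' with the origin at the top-left corner, rows increasing downwards. This
#' matches how per-frame ROI tables are written to disk; helpers below convert
#' to R's 1-based matrix indices.
#'
#' @param r0,c0 Top-left corner (inclusive), 0-based.
#' @param r1,c1 Bottom-right corner (exclusive), 0-based.
#' @return An object of class `"roi"`.
#' @examples
#' r <- roi(2, 3, 6, 9)
#' roi_area(r)
#' @export
roi <- function(r0, c0, r1, c1) {
  vals <- c(r0 = r0, c0 = c0, r1 = r1, c1 = c1)
  if (!all(is.finite(vals)) || any(vals != round(vals))) {
    abort("ROI coordinates must be finite integers")
  }
  if (!(r0 < r1 && c0 < c1)) {
    abort("empty ROI: need r0 < r1 and c0 < c1")
  }
  if (r0 < 0 || c0 < 0) abort("ROI coordinates must be non-negative")
  structure(
    list(r0 = as.integer(r0), c0 = as.integer(c0),
         r1 = as.integer(r1), c1 = as.integer(c1)),
    class = "roi"
  )
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> rows [%d, %d) x cols [%d, %d), area %d px\n",
              x$r0, x$r1, x$c0, x$c1, roi_area(x)))
  invisible(x)
}

#' @rdname roi
#' @param x An `roi`.
#' @export
roi_area <- function(x) (x$r1 - x$r0) * (x$c1 - x$c0)

# 1-based row / column index vectors for matrix subsetting
roi_rows <- function(x) (x$r0 + 1L):x$r1
roi_cols <- function(x) (x$c0 + 1L):x$c1

# centroid in continuous 0-based coordinates (centre of covered area)
roi_centroid <- function(x) c((x$r0 + x$r1) / 2, (x$c0 + x$c1) / 2)

roi_in_frame <- function(x, dim) {
  x$r0 >= 0 && x$c0 >= 0 && x$r1 <= dim[1] && x$c1 <= dim[2]
}

roi_crop <- function(m, x) {
  if (!roi_in_frame(x, dim(m))) abort("ROI extends outside the frame")
  m[roi_rows(x), roi_cols(x), drop = FALSE]
}

#' Intersection-over-union of two ROIs
#'
#' @param a,b `roi` objects.
#' @return Jaccard overlap in `[0, 1]`.
#' @export
roi_iou <- function(a, b) {
  ir <- max(0L, min(a$r1, b$r1) - max(a$r0, b$r0))
  ic <- max(0L, min(a$c1, b$c1) - max(a$c0, b$c0))
  inter <- ir * ic
  inter / (roi_area(a) + roi_area(b) - inter)
}

roi_to_row <- function(x) {
  tibble(r0 = x$r0, c0 = x$c0, r1 = x$r1, c1 = x$c1)
}
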