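#' Calibration-bar layout
#'
#' Describes where the calibration bar sits in a thermal frame and where the
#' printed minimum and maximum temperatures are, as fixed-width character
#' cells. The first cell of each field holds the sign (minus or blank); the
#' remaining cells hold a zero-padded value with one decimal place, e.g.
#' `-040.0` or `330.0` for the camera limits.
#'
#' @param frame_shape `(rows, cols)` of the full frame the bar is embedded in.
#' @param n_cells Character cells per temperature field (sign cell included).
#' @param cell_shape `(rows, cols)` of one character cell.
#' @return A `"bar_layout"` with the bar box, per-cell boxes for both fields,
#'   the grey-gradient strip, and the image (face) region below the bar.
#' @export
bar_layout <- function(frame_shape, n_cells = 6L, cell_shape = c(11L, 6L)) {
  rows <- as.integer(frame_shape[1]); cols <- as.integer(frame_shape[2])
  bar_rows <- cell_shape[1] + 3L            # text band + gradient strip
  field_w <- n_cells * cell_shape[2]
  if (cols < 2L * field_w + 8L) {
    abort(sprintf("frame of width %d cannot hold two %d-cell temperature fields",
                  cols, n_cells))
  }
  if (rows <= bar_rows + 1L) abort("frame too short to hold a bar and an image")
  cell_boxes <- function(col_start) {
    lapply(seq_len(n_cells) - 1L, function(i) {
      roi(1L, col_start + i * cell_shape[2],
          1L + cell_shape[1], col_start + (i + 1L) * cell_shape[2])
    })
  }
  structure(
    list(
      bar_box = roi(0L, 0L, bar_rows, cols),
      min_cells = cell_boxes(2L),
      max_cells = cell_boxes(cols - 2L - field_w),
      gradient_box = roi(cell_shape[1] + 1L, 0L, bar_rows, cols),
      image_box = roi(bar_rows, 0L, rows, cols),
      cell_shape = as.integer(cell_shape),
      n_cells = as.integer(n_cells),
      frame_shape = c(rows, cols)
    ),
    class = "bar_layout"
  )
}

#' @export
print.bar_layout <- function(x, ...) {
  cat(sprintf("<bar_layout> frame %dx%d, bar %d rows, 2 fields of %d cells (%dx%d px)\n",
              x$frame_shape[1], x$frame_shape[2], x$bar_box$r1,
              x$n_cells, x$cell_shape[1], x$cell_shape[2]))
  invisible(x)
}

# Split a temperature into per-cell characters: sign cell then a zero-padded
# fixed-point value with one decimal. Errors if the value needs more cells.
format_bar_value <- function(x, n_cells) {
  body <- formatC(abs(x), format = "f", digits = 1, width = n_cells - 1L,
                  flag = "0")
  if (nchar(body) > n_cells - 1L) {
    abort(sprintf("temperature %.1f does not fit in %d character cells", x, n_cells))
  }
  c(if (x < 0) "-" else " ", strsplit(body, "")[[1]])
}

#' Render a calibration bar
#'
#' Draws the bar strip that the synthetic thermal camera embeds in every
#' frame: the frame's minimum and maximum temperatures printed as raster
#' glyphs over a uniform background, plus a full 0-255 grey gradient strip.
#'
#' @param tmin,tmax Temperatures in degC, `tmin < tmax`, both within the
#'   camera range -40 to 330 degC.
#' @param layout A [bar_layout()].
#' @return Integer grey matrix (0-255) of the bar region.
#' @examples
#' lay <- bar_layout(c(56, 80))
#' bar <- render_calibration_bar(22.4, 31.7, lay)
#' @export
render_calibration_bar <- function(tmin, tmax, layout) {
  stopifnot(inherits(layout, "bar_layout"))
  if (!is.finite(tmin) || !is.finite(tmax) || tmin >= tmax) {
    abort("need finite tmin < tmax")
  }
  if (tmin < -40 || tmax > 330) abort("temperatures outside the -40..330 degC camera range")
  bar <- matrix(40L, layout$bar_box$r1, layout$bar_box$c1)
  gcols <- layout$bar_box$c1
  grad <- round(seq(0, 255, length.out = gcols))
  for (r in roi_rows(layout$gradient_box)) bar[r, ] <- grad
  draw_field <- function(bar, value, cells) {
    chars <- format_bar_value(value, length(cells))
    for (i in seq_along(cells)) {
      cell <- render_glyph_cell(chars[i], cell_shape = layout$cell_shape,
                                ink = 255, bg = 40)
      bar[roi_rows(cells[[i]]), roi_cols(cells[[i]])] <- cell
    }
    bar
  }
  bar <- draw_field(bar, tmin, layout$min_cells)
  bar <- draw_field(bar, tmax, layout$max_cells)
  storage.mode(bar) <- "integer"
  bar
}
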