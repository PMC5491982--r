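# 5x7 raster font for the characters the calibration bar can print.
# 1 = ink. The OCR model trains on glyphs rendered from this same font,
# so the exact pixel pattern is a free choice.

.bar_font <- list(
  "0" = c("01110", "10001", "10011", "10101", "11001", "10001", "01110"),
  "1" = c("00100", "01100", "00100", "00100", "00100", "00100", "01110"),
  "2" = c("01110", "10001", "00001", "00010", "00100", "01000", "11111"),
  "3" = c("11111", "00010", "00100", "00010", "00001", "10001", "01110"),
  "4" = c("00010", "00110", "01010", "10010", "11111", "00010", "00010"),
  "5" = c("11111", "10000", "11110", "00001", "00001", "10001", "01110"),
  "6" = c("00110", "01000", "10000", "11110", "10001", "10001", "01110"),
  "7" = c("11111", "00001", "00010", "00100", "01000", "01000", "01000"),
  "8" = c("01110", "10001", "10001", "01110", "10001", "10001", "01110"),
  "9" = c("01110", "10001", "10001", "01111", "00001", "00010", "01100"),
  "." = c("00000", "00000", "00000", "00000", "00000", "01100", "01100"),
  "-" = c("00000", "00000", "00000", "11111", "00000", "00000", "00000")
)

#' Characters the calibration bar can print
#'
#' Digits plus the decimal point and minus sign; the thermal camera range
#' extends below 0 degC and temperatures are printed with one decimal place.
#'
#' @return Character vector of the 12 glyph classes.
#' @export
bar_charset <- function() names(.bar_font)

# 7x5 0/1 matrix for one character
glyph_bitmap <- function(ch) {
  rows <- .bar_font[[ch]]
  if (is.null(rows)) abort(paste0("no glyph for character '", ch, "'"))
  do.call(rbind, lapply(strsplit(rows, ""), function(r) as.integer(r)))
}

# nearest-neighbour resize of a numeric matrix to `shape` = c(rows, cols)
resize_nearest <- function(m, shape) {
  nr <- shape[1]; nc <- shape[2]
  if (all(dim(m) == shape)) return(m)
  ri <- pmin(dim(m)[1], pmax(1L, ceiling(seq_len(nr) / nr * dim(m)[1])))
  ci <- pmin(dim(m)[2], pmax(1L, ceiling(seq_len(nc) / nc * dim(m)[2])))
  m[ri, ci, drop = FALSE]
}

# bilinear resize; preserves thin strokes as partial-intensity pixels, the
# way rasterised overlay text looks after rescaling
resize_bilinear <- function(m, shape) {
  nr <- shape[1]; nc <- shape[2]
  if (all(dim(m) == shape)) return(m)
  src <- function(n_out, n_in) {
    p <- (seq_len(n_out) - 0.5) / n_out * n_in - 0.5
    p <- pmin(pmax(p, 0), n_in - 1)
    lo <- pmin(floor(p) + 1, n_in)
    hi <- pmin(lo + 1, n_in)
    list(lo = lo, hi = hi, w = p - (lo - 1))
  }
  r <- src(nr, nrow(m)); c <- src(nc, ncol(m))
  a <- m[r$lo, c$lo, drop = FALSE] * (1 - r$w) + m[r$hi, c$lo, drop = FALSE] * r$w
  b <- m[r$lo, c$hi, drop = FALSE] * (1 - r$w) + m[r$hi, c$hi, drop = FALSE] * r$w
  sweep(a, 2, 1 - c$w, "*") + sweep(b, 2, c$w, "*")
}

# Render one character into a grey cell matrix. `shift` is (rows, cols);
# `scale` resizes the 7x5 bitmap before centring. Pixels falling outside the
# cell are clipped.
render_glyph_cell <- function(ch, cell_shape = c(11L, 7L), shift = c(0L, 0L),
                              scale = 1, ink = 255, bg = 40) {
  cell <- matrix(bg, cell_shape[1], cell_shape[2])
  if (ch == " " || ch == "") return(cell)
  bm <- glyph_bitmap(ch)
  gs <- pmax(c(1L, 1L), round(dim(bm) * scale))
  bm <- resize_bilinear(bm, gs)
  r0 <- floor((cell_shape[1] - gs[1]) / 2) + 1L + round(shift[1])
  c0 <- floor((cell_shape[2] - gs[2]) / 2) + 1L + round(shift[2])
  for (i in seq_len(gs[1])) {
    for (j in seq_len(gs[2])) {
      ri <- r0 + i - 1L; ci <- c0 + j - 1L
      if (ri >= 1 && ri <= cell_shape[1] && ci >= 1 && ci <= cell_shape[2] &&
          bm[i, j] > 0) {
        cell[ri, ci] <- bg + (ink - bg) * bm[i, j]
      }
    }
  }
  cell
}
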