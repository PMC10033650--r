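# Abstract slide reader: two methods, read_thumbnail() and read_tile().
# Backends: an in-memory high-magnification array, and plain PNG/TIFF
# thumbnail files standing in for the 1.25x level at desk scale.

#' Slide reader over an in-memory high-magnification array
#'
#' Wraps a `[row, col, 3]` pixel array taken to live at `mag_hi`. The
#' thumbnail is produced by mean-pooling with the integer factor
#' `mag_hi / mag_thumb`; tiles are read directly at pixel origins.
#'
#' @param pixels_hi RGB array at the high-magnification level.
#' @param mag_hi,mag_thumb magnifications; their ratio must be an integer.
#' @return object of class `c("array_slide_reader", "slide_reader")`.
#' @export
slide_reader_array <- function(pixels_hi, mag_hi = 20, mag_thumb = 1.25) {
  factor <- mag_hi / mag_thumb
  if (abs(factor - round(factor)) > 1e-9)
    stop_mf("mag_hi/mag_thumb must be an integer factor, got %g", factor,
            class = "mf_config_error")
  structure(list(pixels = pixels_hi, mag_hi = mag_hi, mag_thumb = mag_thumb,
                 factor = as.integer(round(factor))),
            class = c("array_slide_reader", "slide_reader"))
}

#' Slide reader over a plain thumbnail image (PNG/TIFF or array)
#'
#' Desk-scale stand-in: the file *is* the 1.25x thumbnail. High-
#' magnification tiles are served by nearest-neighbour upsampling of the
#' corresponding thumbnail region by `mag_hi / mag_thumb`; no interpolation
#' is invented beyond pixel replication.
#'
#' @param source path to a PNG or TIFF file, or an RGB array.
#' @param mag_thumb,mag_hi magnifications; ratio must be an integer.
#' @return object of class `c("image_slide_reader", "slide_reader")`.
#' @export
slide_reader_image <- function(source, mag_thumb = 1.25, mag_hi = 20) {
  factor <- mag_hi / mag_thumb
  if (abs(factor - round(factor)) > 1e-9)
    stop_mf("mag_hi/mag_thumb must be an integer factor, got %g", factor,
            class = "mf_config_error")
  img <- if (is.character(source)) read_rgb_image(source) else source
  structure(list(thumbnail = img, mag_thumb = mag_thumb, mag_hi = mag_hi,
                 factor = as.integer(round(factor))),
            class = c("image_slide_reader", "slide_reader"))
}

read_rgb_image <- function(path) {
  img <- if (grepl("\\.(tif|tiff)$", tolower(path))) {
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Read the thumbnail of a slide
#' @param reader a slide reader.
#' @param ... passed to methods.
#' @return RGB array at the reader's thumbnail magnification.
#' @export
read_thumbnail <- function(reader, ...) UseMethod("read_thumbnail")

#' @export
read_thumbnail.image_slide_reader <- function(reader, ...) reader$thumbnail

#' @export
read_thumbnail.array_slide_reader <- function(reader, ...) {
  f <- reader$factor
  px <- reader$pixels
  nr <- dim(px)[1] %/% f
  nc <- dim(px)[2] %/% f
  out <- array(0, c(nr, nc, 3L))
  for (ch in 1:3) {
    m <- px[seq_len(nr * f), seq_len(nc * f), ch]
    # mean-pool f x f blocks
    m <- matrix(colMeans(matrix(m, f)), nr)          # pool rows
    m <- t(matrix(colMeans(matrix(t(m), f)), nc))    # pool cols
    out[, , ch] <- m
  }
  out
}

#' Read a high-magnification tile
#'
#' @param reader a slide reader.
#' @param x_hi,y_hi 0-based pixel origin at the high-magnification level
#'   (x = column, y = row).
#' @param side_hi tile side in high-magnification pixels.
#' @param ... passed to methods.
#' @return RGB array `[side_hi, side_hi, 3]`.
#' @export
read_tile <- function(reader, x_hi, y_hi, side_hi = 224L, ...)
  UseMethod("read_tile")

#' @export
read_tile.array_slide_reader <- function(reader, x_hi, y_hi, side_hi = 224L, ...) {
  px <- reader$pixels
  if (y_hi + side_hi > dim(px)[1] || x_hi + side_hi > dim(px)[2])
    stop_mf("tile (%d,%d)+%d exceeds slide extent %dx%d", x_hi, y_hi, side_hi,
            dim(px)[2], dim(px)[1], class = "mf_argument_error")
  px[y_hi + seq_len(side_hi), x_hi + seq_len(side_hi), , drop = FALSE]
}

#' @export
read_tile.image_slide_reader <- function(reader, x_hi, y_hi, side_hi = 224L, ...) {
  f <- reader$factor
  side_thumb <- side_hi / f
  if (abs(side_thumb - round(side_thumb)) > 1e-9)
    stop_mf("side_hi=%d is not a multiple of the magnification factor %d",
            side_hi, f, class = "mf_config_error")
  side_thumb <- as.integer(round(side_thumb))
  r0 <- y_hi %/% f; c0 <- x_hi %/% f
  thumb <- reader$thumbnail
  if (r0 + side_thumb > dim(thumb)[1] || c0 + side_thumb > dim(thumb)[2])
    stop_mf("tile (%d,%d)+%d exceeds thumbnail extent", x_hi, y_hi, side_hi,
            class = "mf_argument_error")
  crop <- thumb[r0 + seq_len(side_thumb), c0 + seq_len(side_thumb), ,
                drop = FALSE]
  idx <- rep(seq_len(side_thumb), each = f)
  crop[idx, idx, , drop = FALSE]
}
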