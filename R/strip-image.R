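#' Strip image container
#'
#' A `strip_image` wraps a matrix (grayscale) or a height x width x 3 array
#' (RGB) of intensity counts on the 8-bit scale \[0, 255\]. Values may be
#' fractional (e.g. after rescaling); file readers produce integer counts.
#'
#' @param pixels Numeric matrix (grayscale) or 3-d array with third dimension
#'   3 (RGB). Values must lie in \[0, 255\].
#' @return A `strip_image` object.
#' @examples
#' img <- strip_image(matrix(128, 4, 6))
#' dim(img$pixels)
#' @export
strip_image <- function(pixels) {
  if (is.matrix(pixels)) {
    channels <- 1L
  } else if (is.array(pixels) && length(dim(pixels)) == 3 && dim(pixels)[3] == 3) {
    channels <- 3L
  } else {
    stop_lfa("lfaquant_format_error",
             "pixels must be a matrix or an H x W x 3 array")
  }
  if (!is.numeric(pixels) || anyNA(pixels)) {
    stop_lfa("lfaquant_format_error", "pixel values must be numeric and non-missing")
  }
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255) {
    stop_lfa("lfaquant_format_error",
             "pixel values outside [0, 255] (got range [%g, %g])", rng[1], rng[2])
  }
  storage.mode(pixels) <- "double"
  structure(
    list(
      pixels = pixels,
      depth = 8L,
      channels = channels,
      height = dim(pixels)[1],
      width = dim(pixels)[2]
    ),
    class = "strip_image"
  )
}

#' @export
print.strip_image <- function(x, ...) {
  kind <- if (x$channels == 1L) "grayscale" else "RGB"
  cat(sprintf("<strip_image %d x %d px, 8-bit %s, range [%g, %g]>\n",
              x$height, x$width, kind,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.strip_image <- function(x) c(x$height, x$width)

#' Rectangular region of interest
#'
#' Coordinates are 0-based and half-open on both axes: the RoI covers rows
#' `row0 .. row0 + height - 1` and columns `col0 .. col0 + width - 1`.
#'
#' @param row0,col0 0-based top-left corner.
#' @param height,width Extent in pixels; both must be >= 1.
#' @return An `roi_rect` object.
#' @examples
#' roi_rect(0, 0, 40, 200)
#' @export
roi_rect <- function(row0, col0, height, width) {
  for (v in list(row0 = row0, col0 = col0, height = height, width = width)) {
    if (!is.numeric(v) || length(v) != 1 || v != as.integer(v)) {
      stop_lfa("lfaquant_config_error", "roi fields must be scalar integers")
    }
  }
  if (row0 < 0 || col0 < 0) {
    stop_lfa("lfaquant_config_error", "roi corner must be nonnegative")
  }
  if (height < 1 || width < 1) {
    stop_lfa("lfaquant_config_error", "roi height and width must be >= 1")
  }
  structure(
    list(row0 = as.integer(row0), col0 = as.integer(col0),
         height = as.integer(height), width = as.integer(width)),
    class = "roi_rect"
  )
}

#' @export
print.roi_rect <- function(x, ...) {
  cat(sprintf("<roi_rect rows [%d, %d), cols [%d, %d)>\n",
              x$row0, x$row0 + x$height, x$col0, x$col0 + x$width))
  invisible(x)
}
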