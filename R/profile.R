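#' Convert a strip image to grayscale
#'
#' Grayscale input is returned unchanged. RGB is converted with BT.601
#' luminance weights (0.299, 0.587, 0.114) and rounded half up; the CMOS
#' readers this emulates capture native grayscale, so any fixed standard is
#' acceptable and this one is documented.
#'
#' @param img A [strip_image].
#' @return A grayscale [strip_image].
#' @examples
#' px <- array(c(100, 150, 200), dim = c(1, 1, 3))
#' to_grayscale(strip_image(px))$pixels  # 141
#' @export
to_grayscale <- function(img) {
  stopifnot(inherits(img, "strip_image"))
  if (img$channels == 1L) return(img)
  px <- img$pixels
  g <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  # indexing drops 1-px dimensions; restore the matrix shape explicitly
  strip_image(matrix(pmin(round_half_up(g), 255), img$height, img$width))
}

#' Crop a strip image to a region of interest
#'
#' @param img A [strip_image].
#' @param roi An [roi_rect]; 0-based, half-open, must lie within the image.
#' @return The cropped [strip_image] (exact sub-grid copy).
#' @examples
#' img <- strip_image(matrix(1:16, 4, 4))
#' crop_roi(img, roi_rect(1, 1, 2, 2))$pixels
#' @export
crop_roi <- function(img, roi) {
  stopifnot(inherits(img, "strip_image"), inherits(roi, "roi_rect"))
  if (roi$row0 + roi$height > img$height) {
    stop_lfa("lfaquant_roi_error",
             "roi bottom edge (row %d) exceeds image height %d",
             roi$row0 + roi$height, img$height)
  }
  if (roi$col0 + roi$width > img$width) {
    stop_lfa("lfaquant_roi_error",
             "roi right edge (col %d) exceeds image width %d",
             roi$col0 + roi$width, img$width)
  }
  rows <- (roi$row0 + 1):(roi$row0 + roi$height)
  cols <- (roi$col0 + 1):(roi$col0 + roi$width)
  if (img$channels == 1L) {
    strip_image(img$pixels[rows, cols, drop = FALSE])
  } else {
    strip_image(img$pixels[rows, cols, , drop = FALSE])
  }
}

#' Collapse a grayscale image to an averaged intensity profile
#'
#' Averages across the transverse axis at every position along the flow
#' axis, improving the signal-to-noise ratio by roughly the square root of
#' the number of pixels averaged.
#'
#' @param img A grayscale [strip_image] (usually the cropped RoI).
#' @param flow_axis `"width"` (default; profile runs along image columns) or
#'   `"height"`.
#' @return An `intensity_profile`: list with `values` (mean counts,
#'   fractional), `positions` (0-based pixel indices along the flow axis,
#'   relative to the input image) and `n_averaged`.
#' @examples
#' img <- strip_image(matrix(c(10, 30, 20, 40, 30, 50), 2, 3))
#' average_profile(img)$values
#' @export
average_profile <- function(img, flow_axis = c("width", "height")) {
  stopifnot(inherits(img, "strip_image"))
  flow_axis <- match.arg(flow_axis)
  if (img$channels != 1L) {
    stop_lfa("lfaquant_format_error", "average_profile expects a grayscale image")
  }
  if (flow_axis == "width") {
    vals <- colMeans(img$pixels)
    n_avg <- img$height
  } else {
    vals <- rowMeans(img$pixels)
    n_avg <- img$width
  }
  structure(
    list(values = as.numeric(vals),
         positions = seq_along(vals) - 1L,
         n_averaged = n_avg),
    class = "intensity_profile"
  )
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("<intensity_profile: %d positions, %d px averaged, range [%.2f, %.2f]>\n",
              length(x$values), x$n_averaged, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.intensity_profile <- function(x) length(x$values)

#' Smooth an intensity profile with a centered moving average
#'
#' Suppresses residual pixel noise before minimum search. Edges use
#' shrunken windows clipped to the profile, so a window of 1 is the
#' identity and the output never extends the input's value range.
#'
#' @param p An `intensity_profile`.
#' @param window Odd window length in pixels, between 1 and the profile
#'   length.
#' @return The smoothed `intensity_profile`.
#' @examples
#' p <- structure(list(values = c(0, 0, 9, 0, 0), positions = 0:4,
#'                     n_averaged = 1L), class = "intensity_profile")
#' smooth_profile(p, 3)$values
#' @export
smooth_profile <- function(p, window = 5L) {
  stopifnot(inherits(p, "intensity_profile"))
  n <- length(p$values)
  if (window %% 2 != 1 || window < 1) {
    stop_lfa("lfaquant_config_error", "smoothing window must be odd and >= 1 (got %s)", window)
  }
  if (window > n) {
    stop_lfa("lfaquant_config_error",
             "smoothing window %d exceeds profile length %d", window, n)
  }
  if (window == 1) return(p)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, p$values))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  p$values <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  p
}

#' Export an intensity profile as CSV
#'
#' @param p An `intensity_profile`.
#' @param path Output CSV path (columns `position_px`, `mean_intensity`,
#'   `n_averaged`).
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(p, path) {
  stopifnot(inherits(p, "intensity_profile"))
  utils::write.csv(
    data.frame(position_px = p$positions,
               mean_intensity = p$values,
               n_averaged = p$n_averaged),
    path, row.names = FALSE)
  invisible(path)
}
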