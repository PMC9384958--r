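#' Synthetic strip phantom configuration
#'
#' Full parametric description of a synthetic lateral-flow strip image:
#' sensor geometry, band optics and noise. Defaults emulate a 640 x 480
#' 8-bit grayscale CMOS capture of a single strip whose flow axis runs left
#' to right, with the test line upstream (left) of the control line. All
#' band geometry is invented: the assay vendor publishes no band widths,
#' spacings or absorbance depths, so these are plausible values chosen for
#' testability, not measurements.
#'
#' The test-band darkness follows a saturating (Langmuir) law
#' `amp_max * c / (c + k_half)`: linear in concentration `c` at low `c`,
#' plateauing at `amp_max`. With the default `amp_max = 160`,
#' `control_amplitude = 80` and `k_half = 300` ng/ml the test band reaches
#' the control-band depth exactly at 300 ng/ml, so the Test-Control ratio
#' of a noise-free strip is 1 at that concentration.
#'
#' @param image_height,image_width Sensor size in pixels.
#' @param roi [roi_rect] analysed region; flow axis along its width.
#' @param background_level Unstained membrane intensity (counts, 0-255).
#' @param control_center Control-line center, absolute image column (px).
#' @param line_spacing Distance between test- and control-line centers (px);
#'   the test line sits `line_spacing` px upstream of the control line.
#' @param band_sigma Gaussian cross-section sd of each band (px).
#' @param control_amplitude Control-band depth below background (counts).
#' @param amp_max Asymptotic test-band depth (counts).
#' @param k_half Concentration at half-maximal test-band depth (ng/ml).
#' @param pixel_noise_sd Additive per-pixel Gaussian noise sd (counts).
#' @param strip_jitter_sd Relative sd of the per-strip multiplicative
#'   amplitude factor (dimensionless); emulates strip-to-strip line
#'   intensity variability.
#' @param illumination_slope Linear illumination ramp along the flow axis
#'   (counts per px, centered on the image).
#' @param rotation_deg Rotation applied last (degrees, nearest-neighbour).
#' @param offset_px Integer translation along the flow axis applied last (px).
#' @return A `phantom_config` object.
#' @examples
#' cfg <- phantom_config()
#' cfg$k_half
#' @export
phantom_config <- function(image_height = 480L,
                           image_width = 640L,
                           roi = roi_rect(220L, 220L, 40L, 200L),
                           background_level = 200,
                           control_center = 370L,
                           line_spacing = 60L,
                           band_sigma = 6,
                           control_amplitude = 80,
                           amp_max = 160,
                           k_half = 300,
                           pixel_noise_sd = 2,
                           strip_jitter_sd = 0.07,
                           illumination_slope = 0,
                           rotation_deg = 0,
                           offset_px = 0L) {
  cfg <- structure(
    list(image_height = as.integer(image_height),
         image_width = as.integer(image_width),
         roi = roi,
         background_level = background_level,
         control_center = control_center,
         line_spacing = line_spacing,
         band_sigma = band_sigma,
         control_amplitude = control_amplitude,
         amp_max = amp_max,
         k_half = k_half,
         pixel_noise_sd = pixel_noise_sd,
         strip_jitter_sd = strip_jitter_sd,
         illumination_slope = illumination_slope,
         rotation_deg = rotation_deg,
         offset_px = as.integer(offset_px)),
    class = "phantom_config"
  )
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  if (!inherits(cfg$roi, "roi_rect")) {
    stop_lfa("lfaquant_config_error", "roi must be an roi_rect")
  }
  if (cfg$image_height < 1 || cfg$image_width < 1) {
    stop_lfa("lfaquant_config_error", "image dimensions must be >= 1")
  }
  roi <- cfg$roi
  if (roi$row0 + roi$height > cfg$image_height ||
      roi$col0 + roi$width > cfg$image_width) {
    stop_lfa("lfaquant_config_error", "roi extends beyond the image")
  }
  if (cfg$background_level < 0 || cfg$background_level > 255) {
    stop_lfa("lfaquant_config_error", "background_level must be in [0, 255]")
  }
  if (cfg$background_level - cfg$control_amplitude < 0) {
    stop_lfa("lfaquant_config_error",
             "control band would undershoot zero (background_level - control_amplitude < 0)")
  }
  if (cfg$amp_max > cfg$background_level) {
    stop_lfa("lfaquant_config_error", "amp_max must not exceed background_level")
  }
  if (cfg$band_sigma <= 0 || cfg$k_half <= 0 || cfg$line_spacing <= 0) {
    stop_lfa("lfaquant_config_error", "band_sigma, k_half and line_spacing must be > 0")
  }
  if (cfg$pixel_noise_sd < 0 || cfg$strip_jitter_sd < 0) {
    stop_lfa("lfaquant_config_error", "noise sds must be >= 0")
  }
  test_center <- cfg$control_center - cfg$line_spacing
  lo <- roi$col0
  hi <- roi$col0 + roi$width - 1
  if (cfg$control_center < lo || cfg$control_center > hi ||
      test_center < lo || test_center > hi) {
    stop_lfa("lfaquant_config_error",
             "band centers (test %d, control %d) must lie inside the roi columns [%d, %d]",
             test_center, cfg$control_center, lo, hi)
  }
  invisible(cfg)
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf(
    paste0("<phantom_config %dx%d px, background %g, bands: test @%d / control @%d ",
           "(sigma %g px), amp_max %g, k_half %g ng/ml, noise sd %g, jitter sd %g>\n"),
    x$image_height, x$image_width, x$background_level,
    x$control_center - x$line_spacing, x$control_center,
    x$band_sigma, x$amp_max, x$k_half, x$pixel_noise_sd, x$strip_jitter_sd))
  invisible(x)
}
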