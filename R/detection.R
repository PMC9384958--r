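#' Line-detection configuration
#'
#' Parameters of the windowed minimum search that locates the control and
#' test lines on an averaged intensity profile.
#'
#' The control line is searched only inside a downstream band of the
#' profile (default fractions 0.55-0.95 of its length) rather than by a
#' global minimum scan: above the concentration where the test band becomes
#' darker than the control band, a global scan would lock onto the test
#' line. The strip sits in a mechanically fixed holder, so a positional
#' prior is justified; the band is configurable.
#'
#' @param control_search_lo,control_search_hi Fractions of the profile
#'   length bounding the control-line search band (0 <= lo < hi <= 1).
#' @param expected_offset Expected test-line center upstream of the control
#'   line (px).
#' @param test_window_halfwidth Half-width of the test-line search window
#'   (px, >= 1).
#' @param line_exclusion_margin Half-width excluded around each detected
#'   line when forming the background region (px, >= 0).
#' @param min_background_px Minimum number of background positions required
#'   for a valid measurement.
#' @return A `detection_config` object.
#' @examples
#' detection_config()
#' @export
detection_config <- function(control_search_lo = 0.55,
                             control_search_hi = 0.95,
                             expected_offset = 60L,
                             test_window_halfwidth = 15L,
                             line_exclusion_margin = 18L,
                             min_background_px = 5L) {
  if (control_search_lo < 0 || control_search_hi > 1 ||
      control_search_lo >= control_search_hi) {
    stop_lfa("lfaquant_config_error",
             "need 0 <= control_search_lo < control_search_hi <= 1")
  }
  if (test_window_halfwidth < 1) {
    stop_lfa("lfaquant_config_error", "test_window_halfwidth must be >= 1")
  }
  if (line_exclusion_margin < 0) {
    stop_lfa("lfaquant_config_error", "line_exclusion_margin must be >= 0")
  }
  structure(
    list(control_search_lo = control_search_lo,
         control_search_hi = control_search_hi,
         expected_offset = as.integer(expected_offset),
         test_window_halfwidth = as.integer(test_window_halfwidth),
         line_exclusion_margin = as.integer(line_exclusion_margin),
         min_background_px = as.integer(min_background_px)),
    class = "detection_config"
  )
}

#' @export
print.detection_config <- function(x, ...) {
  cat(sprintf(
    "<detection_config: control band [%.2f, %.2f), test offset %d +/- %d px, margin %d px>\n",
    x$control_search_lo, x$control_search_hi, x$expected_offset,
    x$test_window_halfwidth, x$line_exclusion_margin))
  invisible(x)
}

#' Locate the control line on an averaged profile
#'
#' Returns the position and value of the lowest profile value inside the
#' configured search band; ties are broken towards the smallest position. A
#' constant (flat) profile inside the band means no control line formed,
#' which invalidates the whole test.
#'
#' @param p An `intensity_profile` of length >= 10.
#' @param cfg A [detection_config].
#' @return List with `position` (0-based px) and `value` (counts).
#' @export
detect_control <- function(p, cfg = detection_config()) {
  stopifnot(inherits(p, "intensity_profile"))
  n <- length(p$values)
  if (n < 10) {
    stop_lfa("lfaquant_config_error", "profile too short for detection (length %d < 10)", n)
  }
  idx <- which(p$positions >= cfg$control_search_lo * n &
               p$positions < cfg$control_search_hi * n)
  if (length(idx) == 0) {
    stop_lfa("lfaquant_config_error", "empty control search band")
  }
  band <- p$values[idx]
  if (max(band) == min(band)) {
    stop_lfa("lfaquant_no_control_line",
             "no control line: profile is constant in the search band (flag no_control_line)")
  }
  i <- idx[which.min(band)]  # which.min takes the first minimum: smallest position
  list(position = p$positions[i], value = p$values[i])
}

#' Locate the test line given the control-line position
#'
#' Scans for the minimum inside a window centered `expected_offset` px
#' upstream of the control line, clipped to the profile; ties break towards
#' the smallest position.
#'
#' @param p An `intensity_profile`.
#' @param control_pos Detected control-line position (0-based px).
#' @param cfg A [detection_config].
#' @return List with `position` and `value`.
#' @export
detect_test <- function(p, control_pos, cfg = detection_config()) {
  stopifnot(inherits(p, "intensity_profile"))
  center <- control_pos - cfg$expected_offset
  lo <- center - cfg$test_window_halfwidth
  hi <- center + cfg$test_window_halfwidth
  idx <- which(p$positions >= lo & p$positions <= hi)
  if (length(idx) == 0) {
    stop_lfa("lfaquant_test_window_out_of_profile",
             "test window [%d, %d] lies outside the profile", lo, hi)
  }
  i <- idx[which.min(p$values[idx])]
  list(position = p$positions[i], value = p$values[i])
}

#' Background mean and sd between the detected lines
#'
#' The background region is the stretch of profile strictly between the
#' test and control lines, with `line_exclusion_margin` px dropped next to
#' each line so band tails do not contaminate the estimate.
#'
#' @param p An `intensity_profile`.
#' @param test_pos,control_pos Detected line positions (test upstream).
#' @param cfg A [detection_config].
#' @return List with `mean`, `sd` (sample sd, 0 if a single position) and
#'   `n` (positions used).
#' @export
background_stats <- function(p, test_pos, control_pos, cfg = detection_config()) {
  stopifnot(inherits(p, "intensity_profile"))
  if (test_pos >= control_pos) {
    stop_lfa("lfaquant_config_error",
             "test position (%s) must be upstream of control position (%s)",
             test_pos, control_pos)
  }
  m <- cfg$line_exclusion_margin
  idx <- which(p$positions > test_pos + m & p$positions < control_pos - m)
  if (length(idx) < cfg$min_background_px) {
    stop_lfa("lfaquant_background_too_small",
             "background region has %d px, need >= %d (flag background_too_small)",
             length(idx), cfg$min_background_px)
  }
  v <- p$values[idx]
  list(mean = mean(v),
       sd = if (length(v) > 1) stats::sd(v) else 0,
       n = length(idx))
}

#' Background-normalised intensity ratios
#'
#' The three line-darkness metrics: Test-Background and Control-Background
#' (line minimum over background mean) and Test-Control (test minimum over
#' control minimum). Dividing by a common reference cancels multiplicative
#' illumination changes. For a visible line the ratio is below 1 and
#' decreases as the line darkens with concentration.
#'
#' @param test_value,control_value Line minima (counts).
#' @param background_mean Background mean (counts, > 0).
#' @return List with `ratio_tb`, `ratio_cb`, `ratio_tc`.
#' @examples
#' compute_ratios(120, 120, 200)
#' @export
compute_ratios <- function(test_value, control_value, background_mean) {
  if (background_mean <= 0) {
    stop_lfa("lfaquant_config_error", "background_mean must be > 0")
  }
  if (control_value <= 0) {
    stop_lfa("lfaquant_config_error", "control_value must be > 0")
  }
  list(ratio_tb = test_value / background_mean,
       ratio_cb = control_value / background_mean,
       ratio_tc = test_value / control_value)
}

#' Analyse a single strip image end to end
#'
#' Composes the full per-strip chain: grayscale conversion, RoI crop,
#' transverse averaging, smoothing, control- and test-line detection,
#' background statistics and ratio computation. Every intermediate is kept
#' in the returned audit record.
#'
#' @param img A [strip_image] (grayscale or RGB).
#' @param roi An [roi_rect] selecting the analysed window.
#' @param cfg A [detection_config].
#' @param smooth_window Odd moving-average window applied before detection
#'   (px; 1 disables smoothing).
#' @param flow_axis `"width"` or `"height"`, passed to [average_profile()].
#' @return A `strip_measurement`: detected positions/values, background
#'   mean/sd, the three ratios, quality `flags`, and an `audit` list with
#'   the raw and smoothed profiles, the RoI and configs.
#' @examples
#' cfg <- phantom_config(pixel_noise_sd = 0, strip_jitter_sd = 0)
#' s <- render_strip(300, cfg)
#' analyze_strip(s$image, cfg$roi)
#' @export
analyze_strip <- function(img, roi, cfg = detection_config(),
                          smooth_window = 5L, flow_axis = "width") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_lfa("lfaquant_stage_error", "[%s] %s", name, conditionMessage(e))
    })
  }
  gray <- stage("to_grayscale", to_grayscale(img))
  cropped <- stage("crop_roi", crop_roi(gray, roi))
  raw_profile <- stage("average_profile", average_profile(cropped, flow_axis))
  profile <- stage("smooth_profile", smooth_profile(raw_profile, smooth_window))
  ctrl <- stage("detect_control", detect_control(profile, cfg))
  test <- stage("detect_test", detect_test(profile, ctrl$position, cfg))
  bg <- stage("background_stats",
              background_stats(profile, test$position, ctrl$position, cfg))
  ratios <- stage("compute_ratios",
                  compute_ratios(test$value, ctrl$value, bg$mean))

  structure(
    list(control_pos = ctrl$position,
         control_value = ctrl$value,
         test_pos = test$position,
         test_value = test$value,
         background_mean = bg$mean,
         background_sd = bg$sd,
         ratio_tb = ratios$ratio_tb,
         ratio_cb = ratios$ratio_cb,
         ratio_tc = ratios$ratio_tc,
         flags = character(0),
         audit = list(roi = roi,
                      detection_config = cfg,
                      smooth_window = as.integer(smooth_window),
                      flow_axis = flow_axis,
                      raw_profile = raw_profile,
                      smoothed_profile = profile,
                      background_n = bg$n)),
    class = "strip_measurement"
  )
}

#' @export
print.strip_measurement <- function(x, ...) {
  cat("<strip_measurement>\n")
  cat(sprintf("  test line:    pos %4d  value %8.3f\n", x$test_pos, x$test_value))
  cat(sprintf("  control line: pos %4d  value %8.3f\n", x$control_pos, x$control_value))
  cat(sprintf("  background:   mean %7.3f  sd %.3f (n = %d)\n",
              x$background_mean, x$background_sd, x$audit$background_n))
  cat(sprintf("  ratios: T/B %.4f  C/B %.4f  T/C %.4f\n",
              x$ratio_tb, x$ratio_cb, x$ratio_tc))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# Flatten a measurement for CSV/JSON export.
measurement_row <- function(m) {
  data.frame(test_pos = m$test_pos, test_value = m$test_value,
             control_pos = m$control_pos, control_value = m$control_value,
             background_mean = m$background_mean, background_sd = m$background_sd,
             ratio_tb = m$ratio_tb, ratio_cb = m$ratio_cb, ratio_tc = m$ratio_tc,
             stringsAsFactors = FALSE)
}
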