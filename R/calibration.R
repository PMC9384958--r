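#' Per-concentration replicate statistics
#'
#' Groups strip measurements by concentration label and returns the mean
#' and sample standard deviation (n - 1 denominator; 0 for singletons) of
#' the selected ratio.
#'
#' @param measurements List of `strip_measurement` objects (or a numeric
#'   vector of ratios).
#' @param concentrations Concentration label for each measurement (ng/ml).
#' @param ratio_kind `"tb"`, `"cb"` or `"tc"`; ignored when `measurements`
#'   is already numeric.
#' @return Data frame of calibration points: `concentration`, `mean_ratio`,
#'   `sd_ratio`, `n_replicates`, sorted by concentration.
#' @examples
#' replicate_stats(c(0.5, 0.7, 0.6, 0.6), c(100, 100, 200, 200))
#' @export
replicate_stats <- function(measurements, concentrations,
                            ratio_kind = c("tb", "cb", "tc")) {
  ratio_kind <- match.arg(ratio_kind)
  ratios <- extract_ratios(measurements, ratio_kind)
  if (length(ratios) != length(concentrations)) {
    stop_lfa("lfaquant_config_error",
             "measurements (%d) and concentration labels (%d) differ in length",
             length(ratios), length(concentrations))
  }
  if (length(ratios) == 0) {
    stop_lfa("lfaquant_config_error", "no measurements supplied")
  }
  groups <- split(ratios, concentrations)
  conc <- as.numeric(names(groups))
  out <- data.frame(
    concentration = conc,
    mean_ratio = vapply(groups, mean, 0),
    sd_ratio = vapply(groups, function(g) if (length(g) > 1) stats::sd(g) else 0, 0),
    n_replicates = vapply(groups, length, 0L),
    row.names = NULL
  )
  out[order(out$concentration), , drop = FALSE]
}

extract_ratios <- function(measurements, ratio_kind) {
  if (is.numeric(measurements)) return(as.numeric(measurements))
  field <- paste0("ratio_", ratio_kind)
  vapply(measurements, function(m) {
    if (!inherits(m, "strip_measurement")) {
      stop_lfa("lfaquant_config_error",
               "measurements must be strip_measurement objects or numeric ratios")
    }
    m[[field]]
  }, 0)
}

#' Fit a quadratic calibration curve
#'
#' Unweighted least-squares fit of mean ratio on concentration,
#' `ratio = a0 + a1 c + a2 c^2`, using the calibration points that fall
#' inside the requested working range. The stored curve must be strictly
#' decreasing over its working range: if the fitted parabola opens upwards
#' and its vertex lands inside the range (which happens whenever the
#' underlying response saturates within it), the stored `working_hi` is
#' trimmed to the vertex so that inversion is restricted to the decreasing
#' limb. A curve that is not decreasing at `working_lo` is rejected.
#'
#' @param points Data frame from [replicate_stats()] (columns
#'   `concentration`, `mean_ratio`; `sd_ratio`/`n_replicates` used only by
#'   the weighted fit).
#' @param ratio_kind Which ratio the points are, `"tb"` (default), `"cb"`
#'   or `"tc"`; recorded in the curve.
#' @param working_range Length-2 numeric, requested inversion range in
#'   ng/ml (default `c(0, 600)`, the span over which the response is close
#'   to linear before it plateaus).
#' @param weighted If `TRUE`, weight points by `n_replicates / sd_ratio^2`
#'   (points with zero sd get the largest finite weight present).
#' @return An object of class `lfa_calibration` with components
#'   `coefficients` (named `a0`, `a1`, `a2`), `working_lo`, `working_hi`
#'   (possibly trimmed), `requested_hi`, `trimmed`, `residual_rmse`,
#'   `ratio_kind`, and the fitted `points`.
#' @examples
#' pts <- data.frame(concentration = c(0, 200, 400, 600),
#'                   mean_ratio = 1 - 0.001 * c(0, 200, 400, 600))
#' fit <- fit_calibration(pts)
#' coef(fit)
#' @export
fit_calibration <- function(points,
                            ratio_kind = c("tb", "cb", "tc"),
                            working_range = c(0, 600),
                            weighted = FALSE) {
  ratio_kind <- match.arg(ratio_kind)
  if (!is.data.frame(points) ||
      !all(c("concentration", "mean_ratio") %in% names(points))) {
    stop_lfa("lfaquant_config_error",
             "points must be a data frame with concentration and mean_ratio")
  }
  wlo <- working_range[1]; whi <- working_range[2]
  if (!(whi > wlo) || wlo < 0) {
    stop_lfa("lfaquant_config_error", "need working_hi > working_lo >= 0")
  }
  use <- points$concentration >= wlo & points$concentration <= whi
  pts <- points[use, , drop = FALSE]
  if (length(unique(pts$concentration)) < 3) {
    stop_lfa("lfaquant_config_error",
             "need >= 3 distinct concentrations inside the working range (got %d)",
             length(unique(pts$concentration)))
  }
  w <- NULL
  if (weighted) {
    sd2 <- pts$sd_ratio^2
    w <- pts$n_replicates / sd2
    if (any(!is.finite(w))) {
      fin <- w[is.finite(w)]
      w[!is.finite(w)] <- if (length(fin)) max(fin) else 1
    }
  }
  fit <- stats::lm(mean_ratio ~ concentration + I(concentration^2),
                   data = pts, weights = w)
  co <- unname(stats::coef(fit))
  a0 <- co[1]; a1 <- co[2]; a2 <- co[3]

  deriv_at <- function(c) a1 + 2 * a2 * c
  if (deriv_at(wlo) >= 0) {
    stop_lfa("lfaquant_non_monotone_calibration",
             "non_monotone_calibration: fitted curve is not decreasing at working_lo = %g",
             wlo)
  }
  trimmed <- FALSE
  whi_eff <- whi
  if (a2 > 0) {
    vertex <- -a1 / (2 * a2)
    if (vertex < whi) {
      whi_eff <- vertex
      trimmed <- TRUE
    }
  }
  if (whi_eff <= wlo) {
    stop_lfa("lfaquant_non_monotone_calibration",
             "non_monotone_calibration: decreasing limb collapses at working_lo")
  }

  structure(
    list(coefficients = c(a0 = a0, a1 = a1, a2 = a2),
         working_lo = wlo,
         working_hi = whi_eff,
         requested_hi = whi,
         trimmed = trimmed,
         residual_rmse = sqrt(mean(stats::resid(fit)^2)),
         ratio_kind = ratio_kind,
         weighted = weighted,
         points = pts,
         n_points = nrow(pts)),
    class = "lfa_calibration"
  )
}

#' Evaluate a calibration curve
#'
#' `predict()` with `newdata` (or a numeric vector of concentrations)
#' evaluates the forward curve concentration -> ratio. With `ratio =`
#' instead, it performs inverse prediction via
#' [estimate_concentration()] and returns that data frame.
#'
#' @param object An `lfa_calibration`.
#' @param newdata Numeric concentrations, or a data frame with a
#'   `concentration` column. Defaults to the calibration points.
#' @param ratio Optional numeric ratios for inverse prediction.
#' @param ... Unused.
#' @return Numeric ratios, or the [estimate_concentration()] data frame
#'   when `ratio` is supplied.
#' @export
predict.lfa_calibration <- function(object, newdata = NULL, ratio = NULL, ...) {
  if (!is.null(ratio)) {
    return(estimate_concentration(object, ratio))
  }
  conc <- if (is.null(newdata)) {
    object$points$concentration
  } else if (is.data.frame(newdata)) {
    newdata$concentration
  } else {
    as.numeric(newdata)
  }
  co <- object$coefficients
  unname(co["a0"] + co["a1"] * conc + co["a2"] * conc^2)
}

#' @export
coef.lfa_calibration <- function(object, ...) object$coefficients

#' @export
fitted.lfa_calibration <- function(object, ...) {
  predict(object, newdata = object$points$concentration)
}

#' @export
residuals.lfa_calibration <- function(object, ...) {
  object$points$mean_ratio - fitted(object)
}

#' @export
print.lfa_calibration <- function(x, ...) {
  co <- x$coefficients
  cat("Quadratic LFA calibration curve\n")
  cat(sprintf("  ratio_%s = %.6g %+.4g c %+.4g c^2   (c in ng/ml)\n",
              x$ratio_kind, co["a0"], co["a1"], co["a2"]))
  cat(sprintf("  working range: [%g, %g] ng/ml%s\n",
              x$working_lo, x$working_hi,
              if (x$trimmed) sprintf(" (trimmed from %g at the curve vertex)", x$requested_hi) else ""))
  cat(sprintf("  points: %d, residual RMSE: %.4g\n", x$n_points, x$residual_rmse))
  invisible(x)
}

#' @export
summary.lfa_calibration <- function(object, ...) {
  print(object)
  cat("\nCalibration points:\n")
  print(object$points, row.names = FALSE)
  invisible(object)
}

#' Plot a calibration curve with its points
#'
#' Base-graphics plot of the mean ratios (with +/- 1 sd error bars when
#' available) and the fitted quadratic over the working range.
#'
#' @param x An `lfa_calibration`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.lfa_calibration <- function(x, ...) {
  pts <- x$points
  grid <- seq(x$working_lo, x$working_hi, length.out = 200)
  graphics::plot(pts$concentration, pts$mean_ratio,
                 xlab = "concentration (ng/ml)",
                 ylab = sprintf("ratio (%s)", x$ratio_kind),
                 ylim = range(c(pts$mean_ratio, predict(x, grid))), ...)
  if (!is.null(pts$sd_ratio) && any(pts$sd_ratio > 0)) {
    graphics::arrows(pts$concentration, pts$mean_ratio - pts$sd_ratio,
                     pts$concentration, pts$mean_ratio + pts$sd_ratio,
                     angle = 90, code = 3, length = 0.03)
  }
  graphics::lines(grid, predict(x, grid))
  invisible(x)
}

#' Estimate concentration from a measured ratio (inverse prediction)
#'
#' Solves the calibration quadratic for concentration, taking the unique
#' root on the curve's working range. Ratios above the curve value at
#' `working_lo` (lighter than a blank) are censored `below_working_range`
#' and clamped to `working_lo`; ratios below the value at `working_hi`
#' (darker than the saturation point) are censored `saturated` and clamped
#' to `working_hi`. Each estimate also carries the exacerbation-risk and
#' visual-band labels from [classify_risk()].
#'
#' @param curve An `lfa_calibration`.
#' @param ratio Numeric vector of measured ratios.
#' @param high_threshold Passed to [classify_risk()].
#' @return Data frame with one row per ratio: `ratio`,
#'   `estimated_concentration`, `censoring` (`"none"`,
#'   `"below_working_range"`, `"saturated"`), `risk_label`, `band_label`.
#' @examples
#' pts <- data.frame(concentration = c(0, 200, 400, 600),
#'                   mean_ratio = 1 - 0.001 * c(0, 200, 400, 600))
#' fit <- fit_calibration(pts)
#' estimate_concentration(fit, 0.7)
#' @export
estimate_concentration <- function(curve, ratio, high_threshold = 250) {
  stopifnot(inherits(curve, "lfa_calibration"))
  co <- curve$coefficients
  a0 <- co["a0"]; a1 <- co["a1"]; a2 <- co["a2"]
  wlo <- curve$working_lo; whi <- curve$working_hi
  r_lo <- unname(a0 + a1 * wlo + a2 * wlo^2)
  r_hi <- unname(a0 + a1 * whi + a2 * whi^2)

  solve_one <- function(r) {
    if (r > r_lo) return(c(wlo, 1))           # below_working_range
    if (r < r_hi) return(c(whi, 2))           # saturated
    if (abs(a2) < 1e-14) {
      c(unname((r - a0) / a1), 0)
    } else {
      disc <- a1^2 - 4 * a2 * (a0 - r)
      disc <- max(disc, 0)
      roots <- c((-a1 - sqrt(disc)) / (2 * a2), (-a1 + sqrt(disc)) / (2 * a2))
      tol <- 1e-9 * max(1, whi)
      inside <- roots[roots >= wlo - tol & roots <= whi + tol]
      c(unname(min(max(inside[1], wlo), whi)), 0)
    }
  }
  res <- t(vapply(ratio, solve_one, c(0, 0)))
  conc <- res[, 1]
  cens <- c("none", "below_working_range", "saturated")[res[, 2] + 1]
  labels <- classify_risk(conc, high_threshold = high_threshold)
  data.frame(ratio = ratio,
             estimated_concentration = conc,
             censoring = cens,
             risk_label = labels$risk_label,
             band_label = labels$band_label,
             stringsAsFactors = FALSE)
}

#' Limit of detection under a separation rule
#'
#' Operationalises the "replicate spreads stop overlapping" criterion: the
#' LOD is the smallest grid concentration whose ratio separates from the
#' blank ratio by more than `k * sigma_r`.
#'
#' @param concentrations Grid of concentrations (ng/ml); must contain 0.
#' @param ratios Ratio at each grid concentration (same length).
#' @param sigma_r Replicate ratio standard deviation (dimensionless,
#'   default 0.07).
#' @param k Separation multiplier (default 2).
#' @return The LOD in ng/ml, or `NA_real_` when no grid concentration
#'   separates ("not reached").
#' @examples
#' cfg <- phantom_config()
#' grid <- c(0, 25, 50, 100, 200)
#' r <- (cfg$background_level - test_band_depth(grid, cfg)) / cfg$background_level
#' lod_estimate(grid, r)
#' @export
lod_estimate <- function(concentrations, ratios, sigma_r = 0.07, k = 2) {
  if (length(concentrations) != length(ratios)) {
    stop_lfa("lfaquant_config_error", "concentrations and ratios differ in length")
  }
  if (!any(concentrations == 0)) {
    stop_lfa("lfaquant_config_error", "LOD grid must include the blank (0 ng/ml)")
  }
  if (sigma_r <= 0) {
    stop_lfa("lfaquant_config_error", "sigma_r must be > 0")
  }
  blank <- ratios[match(0, concentrations)]
  ord <- order(concentrations)
  for (i in ord) {
    c_i <- concentrations[i]
    if (c_i == 0) next
    if (blank - ratios[i] > k * sigma_r) return(c_i)
  }
  NA_real_
}

#' Classify exacerbation risk and visual band from a concentration
#'
#' Risk is `high_risk` at or above `high_threshold` (default 250 ng/ml, the
#' clinically used floor of the high-risk range). Visual bands mimic the
#' semi-quantitative read-out: the defaults interpolate midpoints between
#' the vendor's stated band groups (negative up to 87, low 131-296, high
#' from 444 ng/ml), giving boundaries at 109 and 370 ng/ml.
#'
#' @param concentration Concentration(s) in ng/ml, >= 0.
#' @param high_threshold High-risk threshold, inclusive (ng/ml).
#' @param band_breaks Length-2 increasing vector: negative/low and
#'   low/high visual-band boundaries (ng/ml).
#' @return List with character vectors `risk_label`
#'   (`"negative"`/`"low"`/`"high_risk"`) and `band_label`
#'   (`"negative"`/`"low"`/`"high"`).
#' @examples
#' classify_risk(c(0, 150, 250, 500))
#' @export
classify_risk <- function(concentration, high_threshold = 250,
                          band_breaks = c(109, 370)) {
  if (any(concentration < 0)) {
    stop_lfa("lfaquant_config_error", "concentration must be >= 0")
  }
  if (length(band_breaks) != 2 || band_breaks[1] >= band_breaks[2]) {
    stop_lfa("lfaquant_config_error", "band_breaks must be two increasing values")
  }
  band <- ifelse(concentration < band_breaks[1], "negative",
                 ifelse(concentration < band_breaks[2], "low", "high"))
  risk <- ifelse(concentration >= high_threshold, "high_risk",
                 ifelse(concentration >= band_breaks[1], "low", "negative"))
  list(risk_label = risk, band_label = band)
}
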