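test_that("replicate statistics are per-group mean and sample sd", {
  pts <- replicate_stats(c(0.6, 0.6, 0.6), rep(100, 3))
  expect_equal(pts$mean_ratio, 0.6)
  expect_equal(pts$sd_ratio, 0)

  pts2 <- replicate_stats(c(0.5, 0.7), c(200, 200))
  expect_equal(pts2$mean_ratio, 0.6)
  expect_equal(pts2$sd_ratio, sd(c(0.5, 0.7)))
  expect_equal(pts2$n_replicates, 2L)

  # singletons get sd 0
  one <- replicate_stats(0.8, 50)
  expect_equal(one$sd_ratio, 0)

  expect_error(replicate_stats(numeric(0), numeric(0)),
               class = "lfaquant_config_error")
  expect_error(replicate_stats(c(0.5, 0.7), 100),
               class = "lfaquant_config_error")
})

test_that("replicate statistics from measurements match brute-force recomputation", {
  cfg <- phantom_config()
  ser <- dilution_series(c(0, 296, 667), 5, cfg, seed = 4)
  ms <- lapply(ser$strips, function(s) analyze_strip(s$image, cfg$roi))
  conc <- ser$manifest$concentration_ng_ml
  pts <- replicate_stats(ms, conc, ratio_kind = "tb")

  ratios <- vapply(ms, function(m) m$ratio_tb, 0)
  for (i in seq_len(nrow(pts))) {
    g <- ratios[conc == pts$concentration[i]]
    expect_equal(pts$mean_ratio[i], sum(g) / length(g))
    expect_equal(pts$sd_ratio[i], sqrt(sum((g - mean(g))^2) / (length(g) - 1)))
  }
})

test_that("an exact quadratic is recovered to machine tolerance", {
  conc <- c(0, 100, 250, 400, 600)
  pts <- data.frame(concentration = conc, mean_ratio = 1 - 0.001 * conc)
  fit <- fit_calibration(pts)
  expect_equal(unname(coef(fit)), c(1, -0.001, 0), tolerance = 1e-10)
  expect_lt(fit$residual_rmse, 1e-12)

  # with true curvature
  pts2 <- data.frame(concentration = conc,
                     mean_ratio = 1 - 0.002 * conc + 1e-6 * conc^2)
  fit2 <- fit_calibration(pts2)
  expect_equal(unname(coef(fit2)), c(1, -0.002, 1e-6), tolerance = 1e-8)
})

test_that("coefficients equal the closed-form normal-equation solution", {
  set.seed(8)
  conc <- c(0, 50, 120, 260, 390, 540)
  r <- 1 - 0.0012 * conc + rnorm(6, 0, 0.01)
  pts <- data.frame(concentration = conc, mean_ratio = r)
  fit <- fit_calibration(pts)
  X <- cbind(1, conc, conc^2)
  beta <- solve(t(X) %*% X, t(X) %*% r)
  expect_equal(unname(coef(fit)), as.numeric(beta), tolerance = 1e-8)
})

test_that("the noise-free ladder is near-quadratic inside the working range", {
  cfg <- noisefree_cfg()
  ratios <- vapply(default_ladder(), function(c) {
    analyze_strip(render_strip(c, cfg, 1)$image, cfg$roi)$ratio_tb
  }, 0)
  pts <- replicate_stats(ratios, default_ladder())
  fit <- fit_calibration(pts, ratio_kind = "tb", working_range = c(0, 600))
  expect_lt(fit$residual_rmse, 0.02)
  expect_equal(fit$ratio_kind, "tb")
})

test_that("fit guards: too few points, non-monotone data, vertex trimming", {
  expect_error(
    fit_calibration(data.frame(concentration = c(0, 100),
                               mean_ratio = c(1, 0.9))),
    class = "lfaquant_config_error")

  # increasing response cannot calibrate a darkening line
  up <- data.frame(concentration = c(0, 200, 400, 600),
                   mean_ratio = c(0.5, 0.6, 0.7, 0.8))
  expect_error(fit_calibration(up), class = "lfaquant_non_monotone_calibration")

  # saturating response: upward parabola whose vertex lies inside the
  # requested range -> inversion range trimmed to the decreasing limb
  conc <- c(0, 100, 200, 300, 450, 600)
  sat <- data.frame(concentration = conc,
                    mean_ratio = 1 - 0.8 * conc / (conc + 300))
  fit <- fit_calibration(sat, working_range = c(0, 600))
  expect_true(fit$trimmed)
  expect_lt(fit$working_hi, 600)
  expect_gt(fit$working_hi, 300)
  # stored curve is strictly decreasing over its stored range
  grid <- seq(fit$working_lo, fit$working_hi, length.out = 100)
  expect_true(all(diff(predict(fit, grid)) < 0))
})

test_that("inverse prediction round-trips interior concentrations within 1 ng/ml", {
  conc <- c(0, 100, 250, 400, 600)
  pts <- data.frame(concentration = conc,
                    mean_ratio = 1 - 0.0015 * conc + 8e-7 * conc^2)
  fit <- fit_calibration(pts)
  for (c_true in seq(10, fit$working_hi - 10, by = 25)) {
    r <- predict(fit, c_true)
    est <- estimate_concentration(fit, r)
    expect_equal(est$estimated_concentration, c_true, tolerance = 1 / c_true)
    expect_equal(est$censoring, "none")
  }

  # censoring above the blank and below the saturation value
  hi <- estimate_concentration(fit, 1.2)
  expect_equal(hi$censoring, "below_working_range")
  expect_equal(hi$estimated_concentration, 0)
  lo <- estimate_concentration(fit, predict(fit, fit$working_hi) - 0.05)
  expect_equal(lo$censoring, "saturated")
  expect_equal(lo$estimated_concentration, fit$working_hi)
})

test_that("model methods behave like a classed fit object", {
  conc <- c(0, 150, 300, 450, 600)
  pts <- data.frame(concentration = conc,
                    mean_ratio = 1 - 0.001 * conc, sd_ratio = 0.01,
                    n_replicates = 5L)
  fit <- fit_calibration(pts)
  expect_s3_class(fit, "lfa_calibration")
  expect_named(coef(fit), c("a0", "a1", "a2"))
  expect_length(fitted(fit), nrow(pts))
  expect_equal(unname(fitted(fit) + residuals(fit)), pts$mean_ratio)
  expect_output(print(fit), "working range")
  expect_output(summary(fit), "Calibration points")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("round-trip quantification of noisy strips at 200 ng/ml is accurate", {
  cfg <- phantom_config()
  # calibration from one seed ...
  ser <- dilution_series(default_ladder(), 5, cfg, seed = 21)
  ms <- lapply(ser$strips, function(s) analyze_strip(s$image, cfg$roi))
  pts <- replicate_stats(ms, ser$manifest$concentration_ng_ml)
  fit <- fit_calibration(pts)
  # ... unknowns from separate seeds; pooling batches keeps the median a
  # low-variance estimate of the round-trip error
  ratios <- unlist(lapply(c(77, 78, 79), function(seed) {
    unknowns <- dilution_series(200, 20, cfg, seed = seed)
    vapply(unknowns$strips,
           function(s) analyze_strip(s$image, cfg$roi)$ratio_tb, 0)
  }))
  est <- estimate_concentration(fit, ratios)
  expect_lte(median(abs(est$estimated_concentration - 200) / 200), 0.10)
})

test_that("the LOD rule returns the smallest separating concentration", {
  cfg <- phantom_config()
  grid <- c(0, 25, 50, 100, 200, 400, 800)
  ratios <- (cfg$background_level - test_band_depth(grid, cfg)) / cfg$background_level
  expect_equal(lod_estimate(grid, ratios), 100)

  # vanishing noise: every nonzero concentration separates
  expect_equal(lod_estimate(grid, ratios, sigma_r = 1e-9), 25)
  # huge multiplier: separation never reached
  expect_true(is.na(lod_estimate(grid, ratios, k = 1e6)))
  expect_error(lod_estimate(c(25, 50), ratios[2:3]), class = "lfaquant_config_error")

  # monotone nondecreasing in sigma_r and k
  lods_sigma <- vapply(c(0.01, 0.05, 0.07, 0.12, 0.2),
                       function(s) lod_estimate(grid, ratios, sigma_r = s), 0)
  expect_true(all(diff(lods_sigma) >= 0, na.rm = TRUE))
  lods_k <- vapply(c(0.5, 1, 2, 3, 4),
                   function(k) lod_estimate(grid, ratios, k = k), 0)
  expect_true(all(diff(lods_k) >= 0, na.rm = TRUE))
})

test_that("risk and visual-band labels follow the clinical thresholds", {
  expect_equal(classify_risk(250)$risk_label, "high_risk")
  expect_equal(classify_risk(249.9)$risk_label, "low")
  expect_equal(classify_risk(0)$band_label, "negative")
  expect_equal(classify_risk(0)$risk_label, "negative")
  expect_equal(classify_risk(200)$band_label, "low")
  expect_equal(classify_risk(500)$band_label, "high")
  expect_error(classify_risk(-5), class = "lfaquant_config_error")
  # threshold is configurable
  expect_equal(classify_risk(260, high_threshold = 300)$risk_label, "low")
})
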