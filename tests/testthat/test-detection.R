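test_that("control line is found at the true center with the true depth", {
  cfg <- noisefree_cfg()
  ctr <- rel_centers(cfg)
  for (conc in c(0, 131, 444, 1000)) {
    s <- render_strip(conc, cfg, seed = 1)
    p <- average_profile(crop_roi(s$image, cfg$roi))
    got <- detect_control(p)
    expect_lte(abs(got$position - ctr$control), 1)
  }
  # at 0 ng/ml the unsmoothed control minimum is background - control depth
  s0 <- render_strip(0, cfg, seed = 1)
  p0 <- average_profile(crop_roi(s0$image, cfg$roi))
  expect_equal(detect_control(p0)$value,
               cfg$background_level - cfg$control_amplitude,
               tolerance = 0.5 / 120)
})

test_that("control detection is restricted to its search band and breaks ties left", {
  # two equal minima inside the band: leftmost wins
  v <- rep(100, 200)
  v[c(120, 160)] <- 40
  got <- detect_control(make_profile(v))
  expect_equal(got$position, 119)  # 0-based
  expect_equal(got$value, 40)

  # a deeper dip upstream of the band (a dark test line) is ignored
  v2 <- rep(100, 200)
  v2[91] <- 10   # position 90, below control band
  v2[151] <- 60  # position 150, inside band
  expect_equal(detect_control(make_profile(v2))$position, 150)

  expect_error(detect_control(make_profile(rep(7, 200))),
               class = "lfaquant_no_control_line")
  expect_error(detect_control(make_profile(1:5)), class = "lfaquant_config_error")
})

test_that("test line is found in a window upstream of the control line", {
  cfg <- noisefree_cfg()
  ctr <- rel_centers(cfg)
  s <- render_strip(444, cfg, seed = 1)
  p <- average_profile(crop_roi(s$image, cfg$roi))
  ctrl <- detect_control(p)
  test <- detect_test(p, ctrl$position)
  expect_lte(abs(test$position - ctr$test), 1)

  # blank strip: no test dip, the window is flat background
  s0 <- render_strip(0, cfg, seed = 1)
  p0 <- average_profile(crop_roi(s0$image, cfg$roi))
  t0 <- detect_test(p0, detect_control(p0)$position)
  bg0 <- background_stats(p0, t0$position, detect_control(p0)$position)
  expect_equal(t0$value / bg0$mean, 1, tolerance = 0.01)

  # flat window: leftmost position of the minimum
  flat <- make_profile(rep(50, 200))
  expect_equal(detect_test(flat, 150, detection_config())$position, 75)

  # window pushed outside the profile
  expect_error(detect_test(flat, 20, detection_config()),
               class = "lfaquant_test_window_out_of_profile")
})

test_that("background region statistics are unbiased and guarded", {
  cfg <- noisefree_cfg()
  s <- render_strip(300, cfg, seed = 1)
  p <- average_profile(crop_roi(s$image, cfg$roi))
  ctr <- rel_centers(cfg)
  bg <- background_stats(p, ctr$test, ctr$control)
  expect_equal(bg$mean, cfg$background_level, tolerance = 0.5 / 200)

  wide <- detection_config(line_exclusion_margin = 40L)
  expect_error(background_stats(p, ctr$test, ctr$control, wide),
               class = "lfaquant_background_too_small")
  expect_error(background_stats(p, ctr$control, ctr$test),
               class = "lfaquant_config_error")

  # Monte-Carlo: noisy background mean is unbiased for the background level
  ncfg <- small_cfg()
  ctrs <- rel_centers(ncfg)
  means <- vapply(1:100, function(seed) {
    sn <- render_strip(300, ncfg, seed = seed)
    pn <- average_profile(crop_roi(sn$image, ncfg$roi))
    background_stats(pn, ctrs$test, ctrs$control)$mean
  }, 0)
  expect_lt(abs(mean(means) - ncfg$background_level), 0.5)
})

test_that("ratios are the documented quotients with guarded denominators", {
  r <- compute_ratios(120, 120, 200)
  expect_equal(r$ratio_tb, 0.6)
  expect_equal(r$ratio_cb, 0.6)
  expect_equal(r$ratio_tc, 1.0)
  expect_equal(compute_ratios(200, 120, 200)$ratio_tb, 1)  # blank: test == background
  expect_error(compute_ratios(120, 120, 0), class = "lfaquant_config_error")
  expect_error(compute_ratios(120, 0, 200), class = "lfaquant_config_error")
})

test_that("windowed minimum detection equals a brute-force scan oracle", {
  set.seed(6)
  dcfg <- detection_config()
  for (i in 1:250) {
    n <- sample(60:300, 1)
    v <- runif(n, 0, 255)
    p <- make_profile(v)
    # brute force: exhaustive minimum over the stated control band
    band <- which(p$positions >= dcfg$control_search_lo * n &
                  p$positions < dcfg$control_search_hi * n)
    bf_i <- band[which(v[band] == min(v[band]))[1]]
    got_c <- detect_control(p, dcfg)
    expect_identical(got_c$position, p$positions[bf_i])
    expect_identical(got_c$value, v[bf_i])
    # brute force over the clipped test window
    center <- got_c$position - dcfg$expected_offset
    win <- which(p$positions >= center - dcfg$test_window_halfwidth &
                 p$positions <= center + dcfg$test_window_halfwidth)
    if (length(win)) {
      bf_t <- win[which(v[win] == min(v[win]))[1]]
      got_t <- detect_test(p, got_c$position, dcfg)
      expect_identical(got_t$position, p$positions[bf_t])
    }
  }
})

test_that("analyze_strip composes the chain deterministically with an audit trail", {
  cfg <- noisefree_cfg()
  m1 <- analyze_strip(render_strip(296, cfg, 1)$image, cfg$roi)
  m2 <- analyze_strip(render_strip(296, cfg, 1)$image, cfg$roi)
  expect_identical(unclass(m1)[names(m1) != "audit"],
                   unclass(m2)[names(m2) != "audit"])
  expect_s3_class(m1$audit$raw_profile, "intensity_profile")
  expect_identical(m1$audit$roi, cfg$roi)
  # stage name is attached to propagated failures
  tiny_roi <- roi_rect(0, 0, 4, 4)
  err <- tryCatch(analyze_strip(render_strip(296, cfg, 1)$image, tiny_roi),
                  error = identity)
  expect_match(conditionMessage(err), "\\[")
})

test_that("Test-Background ratio decreases strictly with concentration", {
  cfg <- noisefree_cfg()
  concs <- c(0, 87, 131, 296, 444, 1000)
  ratios <- vapply(concs, function(c) {
    analyze_strip(render_strip(c, cfg, 1)$image, cfg$roi)$ratio_tb
  }, 0)
  expect_true(all(diff(ratios) < 0))
  # unsmoothed, the ratio matches the analytic band depth up to quantisation
  raw <- vapply(concs, function(c) {
    analyze_strip(render_strip(c, cfg, 1)$image, cfg$roi, smooth_window = 1L)$ratio_tb
  }, 0)
  expect_equal(raw,
               (cfg$background_level - test_band_depth(concs, cfg)) / cfg$background_level,
               tolerance = 1.5 / cfg$background_level)
})

test_that("detected test depth tracks the jittered truth on noisy strips", {
  cfg <- phantom_config()  # default noise and jitter
  hits <- 0
  for (seed in 1:50) {
    s <- render_strip(444, cfg, seed = seed)
    m <- analyze_strip(s$image, cfg$roi)
    depth <- m$background_mean - m$test_value
    if (abs(depth - s$truth$true_test_depth) / s$truth$true_test_depth <= 0.10) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 45)
})

test_that("ratios obey the normalisation algebra", {
  cfg <- noisefree_cfg()
  img <- render_strip(296, cfg, 1)$image
  m <- analyze_strip(img, cfg$roi)
  # ratio_tc = ratio_tb / ratio_cb
  expect_equal(m$ratio_tc, m$ratio_tb / m$ratio_cb)

  # multiplicative illumination change cancels in all three ratios
  for (k in c(0.25, 0.6, 0.9)) {
    scaled <- strip_image(img$pixels * k)
    ms <- analyze_strip(scaled, cfg$roi)
    expect_equal(ms$ratio_tb, m$ratio_tb, tolerance = 1e-12)
    expect_equal(ms$ratio_cb, m$ratio_cb, tolerance = 1e-12)
    expect_equal(ms$ratio_tc, m$ratio_tc, tolerance = 1e-12)
  }

  # additive offset k maps ratio_tb to (t + k) / (b + k)
  k <- 30
  shifted <- analyze_strip(strip_image(img$pixels + k), cfg$roi)
  expect_equal(shifted$ratio_tb,
               (m$test_value + k) / (m$background_mean + k),
               tolerance = 1e-12)
})
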