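test_that("linearity check flags clipped exposure series", {
  e <- c(100, 200, 400, 600, 800)
  lin <- checkLinearity(e, 0.01 * e)
  expect_identical(lin$flag, "linear")
  expect_equal(lin$slope, 0.01)
  expect_identical(lin$usable_ms, e)

  clipped <- 0.01 * e; clipped[5] <- 0.6 * clipped[5]
  sat <- checkLinearity(e, clipped)
  expect_identical(sat$flag, "saturated")
  expect_false(800 %in% sat$usable_ms)

  expect_error(checkLinearity(c(100, 200), c(1, 2)))
})

test_that("synthetic exposure series classify ROI kinds correctly", {
  cfg <- noisefree(small_scene(seed = 8, n_large_foci = 5, n_pairs = 0,
                               n_orphan_5p = 15, n_orphan_3p = 0,
                               frac_small_in_nucleus = 0,
                               unit_intensity_au = c(6, 0.1),
                               transcripts_per_large_focus = c(35, 40)))
  es <- generateExposureSeries(cfg, c(100, 200, 400, 600, 800),
                               saturation_au = 30)
  geom <- cfg@geometry
  ## background ROI: far corner free of objects
  bgm <- measureRoiSeries(es, cbind(2, 2), radius_um = 1.5, geom)
  expect_identical(checkLinearity(es$exposures_ms, bgm[1, ])$flag,
                   "linear")
  ## small-focus ROIs stay linear
  sm <- es$truth[es$truth$kind == "small_focus", ]
  smm <- measureRoiSeries(es, sm[, c("x_um", "y_um")], 0.6, geom)
  for (i in seq_len(nrow(smm)))
    expect_identical(checkLinearity(es$exposures_ms, smm[i, ])$flag,
                     "linear")
  ## large-focus core ROIs saturate; core = brightest pixel near the
  ## focus in the highest exposure (ROIs are defined at high exposure)
  lg <- es$truth[es$truth$kind == "large_focus", ]
  hi <- es$images[["800"]]
  s <- geom@px_per_um
  flags <- vapply(seq_len(nrow(lg)), function(k) {
    rows <- pmax(1, round(lg$y_um[k] * s) + (-8:8))
    cols <- pmax(1, round(lg$x_um[k] * s) + (-8:8))
    sub <- hi[rows, cols]
    m <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    core <- cbind((cols[m[2]] - 0.5) / s, (rows[m[1]] - 0.5) / s)
    cm <- measureRoiSeries(es, core, 0.5, geom)
    checkLinearity(es$exposures_ms, cm[1, ])$flag
  }, character(1))
  expect_true(all(flags == "saturated"))
})

test_that("unit intensity calibration is a background-subtracted mean", {
  cal <- calibrateUnitIntensity(c(6, 6, 6))
  expect_equal(cal@unit_intensity_mean_au, 6)
  expect_equal(cal@unit_intensity_sd_au, 0)
  cal2 <- calibrateUnitIntensity(c(8, 9, 10), background_au = c(2, 2))
  expect_equal(cal2@unit_intensity_mean_au, 7)
  expect_error(calibrateUnitIntensity(c(6, 7), saturated = c(TRUE, TRUE)))
  expect_error(calibrateUnitIntensity(6))
})

test_that("calibration on a synthetic cohort recovers the unit mean within 10%", {
  cfg <- wtSceneConfig(seed = 61)
  f <- generateField(cfg)
  geom <- cfg@geometry
  mask <- segmentNuclei(f$images$nuclear, geom)
  cc <- compartmentCounts(f$images$p5, f$images$p3, mask, geom,
                          detail = TRUE)
  sarco <- cc$foci$`5p`$sarcoplasmic
  ints <- sarco$integrated_intensity_au[sarco$size_class == "small"]
  cal <- calibrateUnitIntensity(ints)
  expect_equal(cal@unit_intensity_mean_au, 6.0, tolerance = 0.10)
  expect_gte(cal@n_foci, cal@adequacy_n_required)
})

test_that("nascent counts are intensity ratios, scale-invariant", {
  cal <- calibrateUnitIntensity(c(5, 6, 7))
  est <- estimateNascentCount(c(0, 240), cal)
  expect_equal(est$count, c(0, 40))
  expect_equal(est$count_rounded, c(0, 40))
  ## multiplying all intensities by a gain leaves counts unchanged
  g <- 37.5
  cal_g <- calibrateUnitIntensity(g * c(5, 6, 7))
  expect_equal(estimateNascentCount(g * 240, cal_g)$count,
               estimateNascentCount(240, cal)$count)
})

test_that("per-nucleus transcript estimates recover planted counts", {
  cfg <- wtSceneConfig(seed = 67)
  f <- generateField(cfg)
  geom <- cfg@geometry
  mask <- segmentNuclei(f$images$nuclear, geom)
  cc <- compartmentCounts(f$images$p5, f$images$p3, mask, geom,
                          detail = TRUE)
  sarco <- cc$foci$`5p`$sarcoplasmic
  cal <- calibrateUnitIntensity(
    sarco$integrated_intensity_au[sarco$size_class == "small"])
  det_lg <- cc$foci$`5p`$total
  det_lg <- det_lg[det_lg$size_class == "large", ]
  tr_lg <- f$truth[f$truth$kind == "large_focus", ]
  ## match detected large foci to planted ones by position
  est_err <- c()
  for (k in seq_len(nrow(det_lg))) {
    d <- sqrt((det_lg$x_um[k] - tr_lg$x_um)^2 +
                (det_lg$y_um[k] - tr_lg$y_um)^2)
    j <- which.min(d)
    if (d[j] > 3) next
    est <- estimateNascentCount(det_lg$integrated_intensity_au[k], cal)
    est_err <- c(est_err, abs(est$count - tr_lg$transcripts[j]) /
                   tr_lg$transcripts[j])
  }
  expect_gt(length(est_err), 30)
  expect_lt(mean(est_err), 0.15)
})

test_that("required sample size reproduces the 70-80 focus rule", {
  expect_identical(requiredSampleSize(6.0, 2.7), 78L)
  expect_identical(requiredSampleSize(8.4, 3.5), 67L)
  expect_identical(requiredSampleSize(6.1, 2.7), 76L)
  expect_identical(requiredSampleSize(5, 0), 1L)
  expect_error(requiredSampleSize(0, 1))
  ## decreasing in mean, increasing in sd, scale-free
  expect_lt(requiredSampleSize(8, 2.7), requiredSampleSize(6, 2.7))
  expect_gt(requiredSampleSize(6, 3.5), requiredSampleSize(6, 2.7))
  expect_identical(requiredSampleSize(6, 2.7),
                   requiredSampleSize(60, 27))
})
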