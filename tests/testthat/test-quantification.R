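# IS normalization, ROI summaries, calibration fitting and inverse
# prediction, and the formulation spiking arithmetic.

ratioFixture <- function(a, i) {
  normalizeRatio(makeImage(a, transform = "linear"),
                 makeImage(i, transform = "linear"))
}

test_that("ratio image masks undefined pixels and is jointly scale-invariant", {
  a <- matrix(c(50, 0, 10, 20), 2, 2)
  i <- matrix(c(100, 40, 0, NA), 2, 2)
  r <- imageValues(ratioFixture(a, i))
  expect_identical(r[1, 1], 0.5)
  expect_identical(r[2, 1], 0)        # analyte 0, IS > 0
  expect_true(is.na(r[1, 2]))         # IS 0 -> masked
  expect_true(is.na(r[2, 2]))         # IS missing -> masked
  # joint rescaling (laser-energy drift surrogate) leaves ratios unchanged
  r2 <- imageValues(ratioFixture(a * 7.3, i * 7.3))
  expect_equal(r2, r, tolerance = 1e-12)
  expect_error(ratioFixture(a, matrix(1, 3, 2)), "shape mismatch")
  expect_error(normalizeRatio(logTransform(makeImage(a + 1,
                                                     transform = "linear")),
                              makeImage(i, transform = "linear")),
               "linear-scale")
})

test_that("ROI summaries give median/IQR over usable pixels and flag empties", {
  vals <- matrix(NA_real_, 2, 3)
  vals[1, ] <- c(1, 2, 3)
  img <- makeImage(vals, transform = "linear")
  lab <- matrix(0L, 2, 3)
  lab[1, ] <- 1L
  lab[2, ] <- 2L
  map <- new("RoiLabelMap", labels = lab, origin = c(1L, 1L),
             rois = data.frame(id = 1:2, kind = "calibration-spot",
                               pixel_count = 3L,
                               centroid_row = c(1, 2), centroid_col = 2,
                               annotation = ""))
  sm <- summarizeRoi(img, map)
  expect_equal(sm$median_ratio[1], 2)
  expect_equal(sm$iqr_ratio[1], 1)
  expect_identical(sm$n_pixels_used, c(3L, 0L))
  expect_true(sm$flagged[2])                     # fully masked, kept
  expect_equal(sm$below_detection_fraction, c(0, 1))
})

test_that("the spot median concentrates around the true ratio", {
  # 50-px ROI with multiplicative lognormal noise (sdlog 0.2); the sample
  # median of a lognormal is median-unbiased, with asymptotic SE on the log
  # scale of 1.2533 * sdlog / sqrt(n)
  mu <- 0.8
  set.seed(12)
  for (rep in 1:10) {
    vals <- matrix(mu * exp(rnorm(50, 0, 0.2)), 5, 10)
    img <- makeImage(vals, transform = "linear")
    map <- new("RoiLabelMap", labels = matrix(1L, 5, 10),
               origin = c(1L, 1L),
               rois = data.frame(id = 1L, kind = "calibration-spot",
                                 pixel_count = 50L, centroid_row = 3,
                                 centroid_col = 5.5, annotation = ""))
    sm <- summarizeRoi(img, map)
    expect_lt(abs(log(sm$median_ratio) - log(mu)),
              3 * 1.2533 * 0.2 / sqrt(50))
  }
})

noiseFreeSummaries <- function(alpha, beta, levels = c(0, 4, 8),
                               shiftFrac = c(0, 0, 0)) {
  amounts <- c(0.1, 1, 2.5, 10, 20)
  do.call(rbind, lapply(seq_along(levels), function(k) {
    expand.grid(amount_ng = amounts, replicate = 1:4) |>
      transform(lipid_mg_per_g = levels[k],
                median_ratio = alpha * (1 + shiftFrac[k]) +
                  beta * amount_ng)
  }))
}

test_that("noise-free calibration is recovered to machine precision", {
  sm <- noiseFreeSummaries(alpha = 1, beta = 0.05)
  fit <- fitCalibration(sm)
  pl <- calibrationCoefficients(fit)
  expect_equal(pl$intercept, rep(1, 3), tolerance = 1e-10)
  expect_equal(pl$slope, rep(0.05, 3), tolerance = 1e-10)
  expect_equal(fit@r2, 1, tolerance = 1e-10)
  # no effect present, and the null model already fits exactly
  expect_equal(fit@tests$intercept_p, 1)
  expect_equal(fit@tests$slope_p, 1)
})

test_that("a constructed 10% intercept shift is estimated exactly", {
  sm <- noiseFreeSummaries(alpha = 1, beta = 0.05,
                           shiftFrac = c(0, 0, 0.10))
  fit <- fitCalibration(sm)
  sh <- fit@tests$intercept_shift
  expect_equal(sh$estimate[sh$lipid == "8"], 0.10 * 1, tolerance = 1e-10)
  expect_equal(sh$estimate[sh$lipid == "4"], 0, tolerance = 1e-10)
  expect_equal(fit@tests$slope_shift$estimate, c(0, 0), tolerance = 1e-10)
  expect_equal(fit@tests$intercept_p, 0)   # only the full model is exact
  expect_equal(fit@tests$slope_p, 1)       # additive model already exact
  pl <- calibrationCoefficients(fit)
  expect_equal(pl$intercept[pl$lipid == "8"], 1.1, tolerance = 1e-10)
})

test_that("degenerate designs are rejected with the missing cells named", {
  sm <- noiseFreeSummaries(1, 0.05)
  sm <- sm[!(sm$lipid_mg_per_g == 4 & sm$amount_ng != 0.1), ]
  expect_error(fitCalibration(sm), "lipid level\\(s\\) 4")
  expect_error(fitCalibration(data.frame(median_ratio = 1)),
               "misses column")
})

test_that("a single lipid level fits a plain line without effect tests", {
  sm <- noiseFreeSummaries(0.5, 0.1, levels = 0)
  fit <- fitCalibration(sm)
  pl <- calibrationCoefficients(fit)
  expect_identical(nrow(pl), 1L)
  expect_equal(pl$slope, 0.1, tolerance = 1e-10)
  expect_true(is.na(fit@tests$intercept_p))
})

test_that("inverse prediction inverts the calibration exactly", {
  sm <- noiseFreeSummaries(alpha = 0, beta = 0.1, levels = 0)
  sm$median_ratio <- pmax(sm$median_ratio, 1e-9)
  fit <- fitCalibration(sm)
  pred <- predictConcentration(fit, 1.0)
  expect_equal(pred$amount_ng, 10, tolerance = 1e-6)
  expect_false(pred$below_calibration)

  # round trip: every design amount comes back to machine precision
  sm2 <- noiseFreeSummaries(alpha = 1, beta = 0.05)
  fit2 <- fitCalibration(sm2)
  for (lv in c("0", "4", "8")) {
    sub <- sm2[sm2$lipid_mg_per_g == as.numeric(lv), ]
    back <- predictConcentration(fit2, sub$median_ratio, lipidLevel = lv)
    expect_equal(back$amount_ng, sub$amount_ng, tolerance = 1e-8)
  }

  # below the intercept: clamped to zero and flagged
  low <- predictConcentration(fit2, 0.5, lipidLevel = "0")
  expect_identical(low$amount_ng, 0)
  expect_true(low$below_calibration)
  expect_error(predictConcentration(fit2, 1, lipidLevel = "99"),
               "not among fitted levels")
})

test_that("slopes must be positive for inverse prediction", {
  sm <- noiseFreeSummaries(alpha = 1, beta = 0.05, levels = 0)
  sm$median_ratio <- 2 - sm$median_ratio  # negative slope
  fit <- fitCalibration(sm)
  expect_error(predictConcentration(fit, 1), "not positive")
})

test_that("spiking arithmetic reproduces the formulation recipe", {
  expect_equal(spikeArithmetic(285, 0.25, 714, 0.20), 14.2643,
               tolerance = 1e-4)
  expect_equal(spikeArithmetic(285, 0.25, 714, 0.10), 7.1321,
               tolerance = 1e-4)
  # spikeFraction 1 returns the formulation concentration itself
  expect_equal(spikeArithmetic(285, 0.25, 714, 1),
               285 * 0.25 / 0.999, tolerance = 1e-10)
  expect_error(spikeArithmetic(285, 0.25, 714, 1.2), "spikeFraction")
  expect_error(spikeArithmetic(0, 0.25, 714, 0.5), "volumes")
})

test_that("distribution maps mask background and summarize sections", {
  sl <- generateSlide(distributionSlideSpec(seed = 41))
  tg <- defaultTargets()
  mzOf <- function(r) tg$mz[tg$role == r]
  ratio <- normalizeRatio(extractIonImage(sl$grid, mzOf("analyte")),
                          extractIonImage(sl$grid,
                                          mzOf("internal_standard")))
  map <- segmentTissue(logTransform(
    extractIonImage(sl$grid, mzOf("tissue_marker"))), minAreaPx = 50L)
  fit <- fitCalibration(noiseFreeSummaries(1, 0.05))
  dm <- buildDistributionMap(ratio, map, fit, lipidLevel = "0")
  conc <- imageValues(dm$concentration)
  expect_true(all(is.na(conc[labelMatrix(map) == 0])))  # background masked
  expect_identical(nrow(dm$sections), 3L)
  # the sample section (spike 10 ng) sits near its true amount
  sampleRow <- which.max(dm$sections$median_concentration)
  expect_lt(abs(dm$sections$median_concentration[sampleRow] - 10), 1.5)
})

test_that("untreated sections read as below-calibration", {
  sl <- generateSlide(distributionSlideSpec(sampleSpikeNg = 0, seed = 42))
  tg <- defaultTargets()
  mzOf <- function(r) tg$mz[tg$role == r]
  ratio <- normalizeRatio(extractIonImage(sl$grid, mzOf("analyte")),
                          extractIonImage(sl$grid,
                                          mzOf("internal_standard")))
  map <- segmentTissue(logTransform(
    extractIonImage(sl$grid, mzOf("tissue_marker"))), minAreaPx = 50L)
  fit <- fitCalibration(noiseFreeSummaries(1, 0.05))
  dm <- buildDistributionMap(ratio, map, fit, lipidLevel = "0")
  # locate the untreated (ellipse) section: overlap with truth section 1
  rt <- roiTable(map)
  secLab <- sl$truth$sectionLabels
  unt <- rt$id[which.max(vapply(rt$id, function(i)
    sum(labelMatrix(map) == i & secLab == 1), 0))]
  inUnt <- labelMatrix(map) == unt
  expect_true(all(imageValues(dm$concentration)[inUnt] == 0, na.rm = TRUE))
  expect_gt(mean(dm$concentration@belowDetection[inUnt]), 0.99)
})
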