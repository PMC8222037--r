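# Tissue segmentation, spot detection and design-driven annotation.

test_that("two bright squares segment into two 100-px tissue ROIs", {
  set.seed(2)
  v <- matrix(0, 30, 30)
  v[3:12, 3:12] <- 5
  v[18:27, 15:24] <- 5
  v <- v + matrix(rnorm(900, 0, 0.01), 30, 30)  # break histogram degeneracy
  map <- segmentTissue(makeImage(v), minAreaPx = 20L)
  rt <- roiTable(map)
  expect_identical(nrow(rt), 2L)
  expect_identical(rt$pixel_count, c(100L, 100L))
  expect_identical(unique(rt$kind), "tissue-section")
  # row-major label order by centroid
  expect_lt(rt$centroid_row[1], rt$centroid_row[2])
})

test_that("degenerate images raise 'no tissue found'", {
  flat <- makeImage(matrix(1, 10, 10))
  expect_error(segmentTissue(flat), "no tissue found")
  lin <- makeImage(matrix(1, 10, 10), transform = "linear")
  expect_error(segmentTissue(lin), "log10")
})

test_that("Otsu segmentation is invariant to an affine shift of the log image", {
  set.seed(5)
  v <- matrix(rnorm(400, 0, 0.1), 20, 20)
  v[5:16, 5:16] <- v[5:16, 5:16] + 4
  m1 <- segmentTissue(makeImage(v), minAreaPx = 10L)
  m2 <- segmentTissue(makeImage(v + 2.34), minAreaPx = 10L)
  expect_identical(labelMatrix(m1), labelMatrix(m2))
})

test_that("in-package Otsu agrees with EBImage's on NA-free images", {
  set.seed(9)
  for (i in 1:10) {
    x <- c(rnorm(400, 0.2, 0.05), rnorm(200, 0.8, 0.05))
    x <- pmin(pmax(x, 0), 1)
    ours <- otsuThreshold(x, nbins = 256L)
    eb <- EBImage::otsu(EBImage::Image(matrix(x, 30, 20)),
                        range = c(0, 1), levels = 256L)
    # same histogram resolution: thresholds agree to within one bin
    expect_lt(abs(ours - eb), 2 / 256)
  }
})

test_that("component labeling is 8-connected", {
  v <- matrix(0, 6, 6)
  v[cbind(c(2, 3, 4), c(2, 3, 4))] <- 7  # diagonal chain
  sp <- detectSpots(makeImage(v), threshold = 5.6, minAreaPx = 1L)
  expect_identical(nrow(roiTable(sp)), 1L)
  expect_identical(roiTable(sp)$pixel_count, 3L)
})

test_that("spot detection thresholds on the log scale and is monotone", {
  v <- matrix(0, 10, 10)
  v[4, 4:8] <- 6.0  # one 5-px blob
  img <- makeImage(v)
  sp <- detectSpots(img, threshold = 5.6, minAreaPx = 1L)
  expect_identical(roiTable(sp)$pixel_count, 5L)
  expect_identical(unique(roiTable(sp)$kind), "calibration-spot")
  expect_warning(sp2 <- detectSpots(img, threshold = 6.5, minAreaPx = 1L),
                 "no calibration spots")
  expect_identical(nrow(roiTable(sp2)), 0L)
  expect_error(detectSpots(makeImage(v, transform = "linear")), "log10")

  # monotone in the threshold on generated spot images
  tg <- defaultTargets()
  for (seed in 1:3) {
    cs <- generateCalibrationOnly(calibrationSlideSpec(lipidLevels = 0,
                                                       seed = 400L + seed))
    tio <- logTransform(extractIonImage(
      cs$grid, tg$mz[tg$role == "spot_marker"]))
    counts <- vapply(c(0.5, 3, 5.6, 6.5, 8), function(th)
      nrow(roiTable(suppressWarnings(
        detectSpots(tio, threshold = th, minAreaPx = 1L)))), 0L)
    expect_identical(counts[3], 20L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("area band filters undersized and oversized components", {
  v <- matrix(0, 20, 20)
  v[2:3, 2:3] <- 6       # 4 px: below min
  v[6:8, 6:8] <- 6       # 9 px: keep
  v[12:19, 10:19] <- 6   # 80 px: above max
  sp <- detectSpots(makeImage(v), threshold = 5.6, minAreaPx = 5L,
                    maxAreaPx = 50L)
  expect_identical(roiTable(sp)$pixel_count, 9L)
})

test_that("design annotation is bijective and strict about mismatches", {
  sl <- generateCalibrationOnly(calibrationSlideSpec(lipidLevels = 0,
                                                     seed = 17))
  tg <- defaultTargets()
  sp <- detectSpots(logTransform(
    extractIonImage(sl$grid, tg$mz[tg$role == "spot_marker"])),
    minAreaPx = 5L, maxAreaPx = 500L)
  expect_identical(nrow(roiTable(sp)), 20L)
  ann <- annotateRois(sp, sl$truth$design)
  rt <- roiTable(ann)
  expect_false(any(is.na(rt$amount_ng)))
  expect_setequal(rt$spot_id, sl$truth$design$spot_id)
  # each annotated spot sits on its design position
  d <- sl$truth$design[match(rt$spot_id, sl$truth$design$spot_id), ]
  expect_true(all(abs(rt$centroid_row - d$row_hint) <= 1))
  expect_true(all(abs(rt$centroid_col - d$col_hint) <= 1))

  # jittered design hints still give the same bijection
  dj <- sl$truth$design
  set.seed(4)
  dj$row_hint <- dj$row_hint + rnorm(nrow(dj), 0, 0.5)
  dj$col_hint <- dj$col_hint + rnorm(nrow(dj), 0, 0.5)
  annj <- annotateRois(sp, dj)
  expect_identical(roiTable(annj)$spot_id, rt$spot_id)

  # a missing spot under strict policy names the unmatched design cell
  missing <- sl$truth$design[-7, ]
  expect_error(annotateRois(sp, missing), "extra detections")
  droppedSpot <- rt$spot_id[rt$id == 7L]  # design cell of the ROI we remove
  lab <- labelMatrix(sp)
  lab[lab == 7L] <- 0L
  lab[lab > 7L] <- lab[lab > 7L] - 1L
  rois <- roiTable(sp)[-7, ]
  rois$id <- seq_len(nrow(rois))
  sp19 <- new("RoiLabelMap", labels = lab, origin = sp@origin, rois = rois)
  err <- tryCatch(annotateRois(sp19, sl$truth$design),
                  error = conditionMessage)
  expect_match(err, "no spot near design cell")
  expect_match(err, droppedSpot, fixed = TRUE)
})

test_that("two spots contending for one design position raise an ambiguity error", {
  v <- matrix(0, 12, 12)
  v[2:3, 2:3] <- 6
  v[2:3, 8:9] <- 6
  sp <- detectSpots(makeImage(v), minAreaPx = 1L)
  design <- data.frame(spot_id = "only", row_hint = 2.5, col_hint = 5.5,
                       conc_ng_per_ul = 5, drop_volume_ul = 0.5,
                       lipid_mg_per_g = 0, replicate = 1)
  err <- tryCatch(annotateRois(sp, design, policy = "partial"),
                  error = conditionMessage)
  expect_match(err, "ambiguous matching")
  expect_match(err, "only")
})

test_that("tissue segmentation recovers generator geometry (single seed)", {
  sl <- generateSlide(distributionSlideSpec(seed = 33))
  tg <- defaultTargets()
  map <- segmentTissue(logTransform(
    extractIonImage(sl$grid, tg$mz[tg$role == "tissue_marker"])),
    minAreaPx = 50L)
  rt <- roiTable(map)
  expect_identical(nrow(rt), 3L)
  secLab <- sl$truth$sectionLabels
  for (i in rt$id) {
    det <- labelMatrix(map) == i
    # match to the truth section sharing most pixels
    best <- which.max(vapply(1:3, function(s) sum(det & secLab == s), 0))
    expect_gte(jaccard(det, secLab == best), 0.95)
  }
})
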