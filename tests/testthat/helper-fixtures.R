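# Shared fixtures and independent oracles, all built in code.

# Minimal grid builder: peaks is a list of two-column matrices (mz, int),
# one per pixel, in the order of coords rows.
makeGrid <- function(coords, peaks, ...) {
  SpectrumGrid(coords,
               mz = lapply(peaks, function(p) as.vector(p[, 1])),
               intensity = lapply(peaks, function(p) as.vector(p[, 2])),
               ...)
}

# Random small centroided grid (uses the ambient RNG; callers set the seed).
randomGrid <- function(nPix = 6L, maxPeaks = 30L,
                       mzRange = c(500, 600)) {
  side <- ceiling(sqrt(nPix))
  cells <- sample(side * side, nPix)
  coords <- cbind(x = (cells - 1L) %% side + 1L,
                  y = (cells - 1L) %/% side + 1L)
  peaks <- lapply(seq_len(nPix), function(i) {
    n <- sample.int(maxPeaks + 1L, 1L) - 1L  # may be empty
    mz <- sort(runif(n, mzRange[1], mzRange[2]))
    mz <- unique(mz)
    cbind(mz, runif(length(mz), 0, 1000))
  })
  makeGrid(coords, peaks, mzRange = mzRange + c(-1, 1))
}

# Brute-force extraction oracle: scans every peak of every pixel with a
# plain double loop, independent of the implementation's flattened path.
oracleExtract <- function(grid, targetMz, tolerance,
                          aggregation = "sum") {
  co <- pixelCoords(grid)
  xr <- range(co[, 1]); yr <- range(co[, 2])
  vals <- matrix(NA_real_, yr[2] - yr[1] + 1L, xr[2] - xr[1] + 1L)
  pks <- peakLists(grid)
  for (i in seq_len(nrow(co))) {
    acc <- if (aggregation == "sum") 0 else -Inf
    hit <- FALSE
    p <- pks[[i]]
    for (j in seq_len(nrow(p))) {
      if (abs(p[j, 1] - targetMz) <= tolerance) {
        hit <- TRUE
        acc <- if (aggregation == "sum") acc + p[j, 2] else max(acc, p[j, 2])
      }
    }
    vals[co[i, 2] - yr[1] + 1L, co[i, 1] - xr[1] + 1L] <-
      if (hit) acc else 0
  }
  vals
}

# Wrap a plain matrix as an IonImage (for segmentation tests that start
# from a constructed image rather than a grid).
makeImage <- function(values, transform = "log10", tolerance = 0.005) {
  new("IonImage", values = values,
      belowDetection = matrix(FALSE, nrow(values), ncol(values)),
      origin = c(1L, 1L), targetMz = 500, tolerance = tolerance,
      transform = transform, aggregation = "sum", target = "fixture",
      source = "fixture")
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# One full calibration cycle on a generated slide: extract the three
# channels the fit needs, detect + annotate spots, normalize, summarize.
calibrationSummaries <- function(slide, tolerance = 0.005,
                                 threshold = 5.6) {
  tg <- defaultTargets()
  mzOf <- function(role) tg$mz[tg$role == role]
  an <- extractIonImage(slide$grid, mzOf("analyte"), tolerance)
  is <- extractIonImage(slide$grid, mzOf("internal_standard"), tolerance)
  tio <- extractIonImage(slide$grid, mzOf("spot_marker"), tolerance)
  spots <- detectSpots(logTransform(tio), threshold = threshold,
                       minAreaPx = 5L, maxAreaPx = 500L)
  spots <- annotateRois(spots, slide$truth$design)
  summarizeRoi(normalizeRatio(an, is), spots)
}
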