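# Ion-image extraction with a fixed symmetric m/z tolerance window, the
# log10 intensity transform, and optional lock-mass recalibration.

.emptyImage <- function(grid) {
  xr <- range(grid@coords[, 1])
  yr <- range(grid@coords[, 2])
  nr <- yr[2] - yr[1] + 1L
  nc <- xr[2] - xr[1] + 1L
  list(values = matrix(NA_real_, nr, nc),
       below = matrix(FALSE, nr, nc),
       origin = c(xr[1], yr[1]))
}

.pixelIndex <- function(grid, origin, nr) {
  # column-major linear index into the image matrix for each pixel
  row <- grid@coords[, 2] - origin[2] + 1L
  col <- grid@coords[, 1] - origin[1] + 1L
  (col - 1L) * nr + row
}

#' Extract an ion image for a target m/z
#'
#' Pixel value = aggregate (sum by default, optionally max) of centroid
#' intensities with `|mz - targetMz| <= tolerance`. The window is symmetric
#' and closed: a centroid at exactly `targetMz +/- tolerance` is included.
#' Scanned pixels with no centroid in the window get 0; unscanned pixels of
#' the bounding box are `NA` (missing, not zero).
#'
#' @param grid A [SpectrumGrid-class].
#' @param targetMz Target m/z (Da); must lie within the grid's declared
#'   m/z range.
#' @param tolerance Half-window in Da (default 0.005).
#' @param aggregation `"sum"` (default, robust to centroid splitting) or
#'   `"max"`.
#' @param target Provenance label for the image.
#' @return An [IonImage-class] on the linear scale.
#' @export
extractIonImage <- function(grid, targetMz, tolerance = 0.005,
                            aggregation = c("sum", "max"),
                            target = NA_character_) {
  stopifnot(is(grid, "SpectrumGrid"))
  aggregation <- match.arg(aggregation)
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("tolerance must be > 0")
  if (targetMz < grid@mzRange[1] || targetMz > grid@mzRange[2])
    stop(sprintf("target m/z %.4f outside dataset range [%.4f, %.4f]",
                 targetMz, grid@mzRange[1], grid@mzRange[2]))
  if (nPixels(grid) == 0L) stop("empty grid")

  im <- .emptyImage(grid)
  idx <- .pixelIndex(grid, im$origin, nrow(im$values))
  im$values[idx] <- 0  # scanned pixels

  lens <- lengths(grid@mz)
  if (sum(lens)) {
    pix <- rep.int(seq_along(lens), lens)
    mz <- unlist(grid@mz, use.names = FALSE)
    it <- unlist(grid@intensity, use.names = FALSE)
    sel <- abs(mz - targetMz) <= tolerance
    if (any(sel)) {
      pixSel <- pix[sel]
      valSel <- it[sel]
      agg <- if (aggregation == "sum") {
        rowsum(valSel, pixSel)
      } else {
        as.matrix(vapply(split(valSel, pixSel), max, 0))
      }
      im$values[idx[as.integer(rownames(agg))]] <- as.vector(agg)
    }
  }
  if (is.na(target)) target <- sprintf("m/z %.4f", targetMz)
  new("IonImage", values = im$values, belowDetection = im$below,
      origin = as.integer(im$origin), targetMz = as.numeric(targetMz),
      tolerance = as.numeric(tolerance), transform = "linear",
      aggregation = aggregation, target = target,
      source = as.character(grid@metadata$source %||% "in-memory"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Log10-transform an ion image
#'
#' Positive values become `log10(value)`; zeros (scanned, nothing detected)
#' become missing and are flagged below-detection; missing pixels stay
#' missing. Transforming an already log10 image is an error.
#'
#' @param img A linear-scale [IonImage-class].
#' @return A log10-scale [IonImage-class].
#' @export
logTransform <- function(img) {
  stopifnot(is(img, "IonImage"))
  if (img@transform != "linear")
    stop("image is already log10-transformed (double transform)")
  v <- img@values
  below <- !is.na(v) & v == 0
  v[below] <- NA_real_
  v[!is.na(v)] <- log10(v[!is.na(v)])
  new("IonImage", values = v, belowDetection = img@belowDetection | below,
      origin = img@origin, targetMz = img@targetMz,
      tolerance = img@tolerance, transform = "log10",
      aggregation = img@aggregation, target = img@target,
      source = img@source)
}

#' Recalibrate the m/z axes against a lock-mass peak
#'
#' Per pixel, the centroid nearest the lock mass within `searchWindow` is
#' taken as the observed lock peak. In `"ppm"` mode (default) all m/z of the
#' pixel are scaled by `lockMz / observed`, which removes a uniform
#' relative (ppm) drift at every mass; `"constant"` mode adds
#' `lockMz - observed` instead. Pixels without a lock peak are left
#' untouched and counted. The recalibration report is stored in
#' `metadata$recalibration` of the returned grid
#' (`n_shifted`, `n_unshifted`, `median_shift_da`, `mode`).
#'
#' @param grid A [SpectrumGrid-class].
#' @param lockMz Lock mass (Da); default is the ferulic-acid matrix ion.
#' @param searchWindow Half-window (Da) for locating the lock peak.
#' @param mode `"ppm"` (multiplicative) or `"constant"` (additive).
#' @return The recalibrated [SpectrumGrid-class].
#' @export
lockMassRecalibrate <- function(grid, lockMz = 195.0657,
                                searchWindow = 0.01,
                                mode = c("ppm", "constant")) {
  stopifnot(is(grid, "SpectrumGrid"))
  mode <- match.arg(mode)
  if (!is.numeric(searchWindow) || searchWindow <= 0)
    stop("searchWindow must be > 0")
  shifts <- rep(NA_real_, nPixels(grid))
  mzList <- grid@mz
  for (i in seq_along(mzList)) {
    mzi <- mzList[[i]]
    d <- abs(mzi - lockMz)
    j <- which.min(d)
    if (length(j) && d[j] <= searchWindow) {
      obs <- mzi[j]
      shifts[i] <- lockMz - obs
      mzList[[i]] <- if (mode == "ppm") mzi * (lockMz / obs)
                     else mzi + (lockMz - obs)
    }
  }
  shifted <- !is.na(shifts)
  newRange <- grid@mzRange
  allmz <- unlist(mzList, use.names = FALSE)
  if (length(allmz))
    newRange <- c(min(newRange[1], min(allmz)),
                  max(newRange[2], max(allmz)))
  md <- grid@metadata
  md$recalibration <- list(
    n_shifted = sum(shifted), n_unshifted = sum(!shifted),
    median_shift_da = if (any(shifted)) median(shifts[shifted]) else NA_real_,
    mode = mode, lock_mz = lockMz)
  new("SpectrumGrid", coords = grid@coords, mz = mzList,
      intensity = grid@intensity, pixelSize = grid@pixelSize,
      mzRange = newRange, polarity = grid@polarity, metadata = md)
}

#' Export an ion image as a CSV matrix
#'
#' Writes the value matrix with `x`/`y` pixel coordinates as column/row
#' headers; missing pixels are empty cells.
#'
#' @param img An [IonImage-class].
#' @param path Output CSV path.
#' @export
writeIonImageCSV <- function(img, path) {
  v <- img@values
  dimnames(v) <- list(
    y = seq_len(nrow(v)) + img@origin[2] - 1L,
    x = seq_len(ncol(v)) + img@origin[1] - 1L)
  write.csv(v, path, na = "")
  invisible(path)
}
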