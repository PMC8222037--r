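# Central S4 containers of the pipeline. Coordinate convention (fixed to
# avoid the classic transposition bug): imzML pixel positions are 1-based,
# x = column, y = row; every image matrix is indexed [row, col], i.e.
# values[y - yMin + 1, x - xMin + 1] for a raster whose bounding box starts
# at (xMin, yMin) = origin.

#' Pixel-indexed centroided MSI dataset
#'
#' Holds per-pixel centroided peak lists with their spatial coordinates, as
#' read from (or written to) an imzML/ibd file pair. Sparse rasters are
#' permitted: pixels absent from `coords` are "unscanned" and become missing
#' values (not zeros) in extracted ion images.
#'
#' @slot coords Integer matrix (nPixels x 2), columns `x`, `y`, 1-based.
#' @slot mz List of numeric vectors, strictly ascending m/z per pixel.
#' @slot intensity List of non-negative numeric vectors, same lengths.
#' @slot pixelSize Numeric(2), pixel size in micrometers (x, y).
#' @slot mzRange Numeric(2), declared acquisition m/z range.
#' @slot polarity `"positive"` or `"negative"`.
#' @slot metadata Named list of free-form metadata.
#' @export
setClass("SpectrumGrid", representation(
  coords = "matrix",
  mz = "list",
  intensity = "list",
  pixelSize = "numeric",
  mzRange = "numeric",
  polarity = "character",
  metadata = "list"
))

setValidity("SpectrumGrid", function(object) {
  n <- nrow(object@coords)
  if (ncol(object@coords) != 2L) return("coords must have two columns (x, y)")
  if (length(object@mz) != n || length(object@intensity) != n)
    return("mz and intensity lists must match the number of pixels")
  if (anyDuplicated(paste(object@coords[, 1], object@coords[, 2])))
    return("pixel coordinates must be unique")
  if (any(object@coords < 1L)) return("coordinates are 1-based (must be >= 1)")
  if (length(object@mzRange) != 2L || diff(object@mzRange) <= 0)
    return("mzRange must be an increasing pair")
  for (i in seq_len(n)) {
    mzi <- object@mz[[i]]
    if (length(mzi) != length(object@intensity[[i]]))
      return(sprintf("pixel %d: mz and intensity lengths differ", i))
    if (length(mzi) > 1L && any(diff(mzi) <= 0))
      return(sprintf("pixel %d: m/z array not strictly ascending", i))
    if (length(mzi) && (mzi[1] < object@mzRange[1] - 1e-6 ||
                        mzi[length(mzi)] > object@mzRange[2] + 1e-6))
      return(sprintf("pixel %d: m/z outside declared mzRange", i))
    if (any(object@intensity[[i]] < 0))
      return(sprintf("pixel %d: negative intensity", i))
  }
  TRUE
})

#' Construct a SpectrumGrid
#'
#' @param coords Integer matrix or data.frame with columns x, y (1-based).
#' @param mz List of strictly ascending numeric m/z vectors, one per pixel.
#' @param intensity List of non-negative intensity vectors, same lengths.
#' @param pixelSize Pixel size in micrometers, length-2 (x, y) or scalar.
#' @param mzRange Declared m/z range; default spans the data.
#' @param polarity Ion polarity.
#' @param metadata Named list.
#' @return A [SpectrumGrid-class].
#' @export
SpectrumGrid <- function(coords, mz, intensity, pixelSize = c(400, 400),
                         mzRange = NULL, polarity = "positive",
                         metadata = list()) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  colnames(coords) <- c("x", "y")
  if (length(pixelSize) == 1L) pixelSize <- rep(pixelSize, 2L)
  if (is.null(mzRange)) {
    allmz <- unlist(mz, use.names = FALSE)
    mzRange <- if (length(allmz)) range(allmz) + c(-1, 1) else c(0, 1)
  }
  new("SpectrumGrid", coords = coords, mz = mz, intensity = intensity,
      pixelSize = as.numeric(pixelSize), mzRange = as.numeric(mzRange),
      polarity = polarity, metadata = metadata)
}

#' @describeIn SpectrumGrid-class Number of pixels.
#' @param x,object A `SpectrumGrid`.
#' @export
setGeneric("nPixels", function(x) standardGeneric("nPixels"))

#' @rdname SpectrumGrid-class
#' @export
setMethod("nPixels", "SpectrumGrid", function(x) nrow(x@coords))

#' @describeIn SpectrumGrid-class Pixel coordinate matrix (x, y).
#' @export
setGeneric("pixelCoords", function(x) standardGeneric("pixelCoords"))

#' @rdname SpectrumGrid-class
#' @export
setMethod("pixelCoords", "SpectrumGrid", function(x) x@coords)

#' @describeIn SpectrumGrid-class Per-pixel peak lists as a list of
#'   two-column matrices (mz, intensity).
#' @export
setGeneric("peakLists", function(x) standardGeneric("peakLists"))

#' @rdname SpectrumGrid-class
#' @export
setMethod("peakLists", "SpectrumGrid", function(x)
  Map(function(m, i) cbind(mz = m, intensity = i), x@mz, x@intensity))

#' @describeIn SpectrumGrid-class Declared acquisition m/z range.
#' @export
setGeneric("mzRange", function(x) standardGeneric("mzRange"))

#' @rdname SpectrumGrid-class
#' @export
setMethod("mzRange", "SpectrumGrid", function(x) x@mzRange)

setMethod("show", "SpectrumGrid", function(object) {
  cat(sprintf(paste0("SpectrumGrid: %d pixels, raster %d x %d, ",
                     "m/z %.3f-%.3f (%s mode)\n"),
              nPixels(object),
              if (nPixels(object)) diff(range(object@coords[, 1])) + 1L else 0L,
              if (nPixels(object)) diff(range(object@coords[, 2])) + 1L else 0L,
              object@mzRange[1], object@mzRange[2], object@polarity))
  npk <- sum(lengths(object@mz))
  cat(sprintf("  %d centroids total, pixel size %g x %g um\n",
              npk, object@pixelSize[1], object@pixelSize[2]))
})

#' Ion image for one target m/z window
#'
#' 2D intensity map over the raster bounding box. `NA` in `values` means
#' "missing" (unscanned pixel, or masked/below-detection after a transform);
#' `0` means scanned with no signal in the window. The `belowDetection`
#' matrix flags scanned pixels whose linear signal was 0 when a log10
#' transform (or ratio masking) was applied.
#'
#' @slot values Numeric matrix, `[row, col]` = `[y, x]` relative to `origin`.
#' @slot belowDetection Logical matrix, same shape.
#' @slot origin Integer(2): (xMin, yMin) pixel coordinate of `values[1, 1]`.
#' @slot targetMz Target m/z (Da); `NA` for derived images such as ratios.
#' @slot tolerance Extraction half-window (Da).
#' @slot transform `"linear"` or `"log10"`.
#' @slot aggregation `"sum"` or `"max"` (within-window centroid aggregation).
#' @slot target Target name (provenance).
#' @slot source Source dataset identifier (provenance).
#' @export
setClass("IonImage", representation(
  values = "matrix",
  belowDetection = "matrix",
  origin = "integer",
  targetMz = "numeric",
  tolerance = "numeric",
  transform = "character",
  aggregation = "character",
  target = "character",
  source = "character"
))

setValidity("IonImage", function(object) {
  if (!identical(dim(object@values), dim(object@belowDetection)))
    return("values and belowDetection must have identical shape")
  if (!object@transform %in% c("linear", "log10"))
    return("transform must be 'linear' or 'log10'")
  if (!is.na(object@tolerance) && object@tolerance <= 0)
    return("tolerance must be > 0")
  if (object@transform == "linear" &&
      any(object@values[!is.na(object@values)] < 0) &&
      !identical(object@target, "concentration"))
    return("linear-scale intensities must be non-negative")
  TRUE
})

#' @describeIn IonImage-class The value matrix (`[row, col]` = `[y, x]`).
#' @param x,object An `IonImage`.
#' @export
setGeneric("imageValues", function(x) standardGeneric("imageValues"))

#' @rdname IonImage-class
#' @export
setMethod("imageValues", "IonImage", function(x) x@values)

setMethod("show", "IonImage", function(object) {
  d <- dim(object@values)
  cat(sprintf("IonImage '%s': %d x %d (rows x cols), %s scale\n",
              object@target, d[1], d[2], object@transform))
  if (!is.na(object@targetMz))
    cat(sprintf("  target m/z %.4f +/- %.4g Da (%s aggregation)\n",
                object@targetMz, object@tolerance, object@aggregation))
  cat(sprintf("  %d missing px, %d below-detection px\n",
              sum(is.na(object@values)), sum(object@belowDetection)))
})

#' Labeled regions of interest on the raster
#'
#' Integer label matrix (0 = background) plus a per-ROI annotation table.
#' Label ids are dense 1..N, ordered row-major by integer-rounded centroid
#' (ties broken by decreasing pixel count).
#'
#' @slot labels Integer matrix, same shape/origin convention as [IonImage-class].
#' @slot origin Integer(2): (xMin, yMin) of `labels[1, 1]`.
#' @slot rois `data.frame` with at least `id`, `kind`
#'   (`"tissue-section"`/`"calibration-spot"`), `pixel_count`,
#'   `centroid_row`, `centroid_col`, `annotation`; annotation joins
#'   (concentration, replicate, lipid level, slide role) add columns.
#' @export
setClass("RoiLabelMap", representation(
  labels = "matrix",
  origin = "integer",
  rois = "data.frame"
))

setValidity("RoiLabelMap", function(object) {
  lab <- object@labels
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) && !identical(as.integer(ids), seq_along(ids)))
    return("label ids must be dense 1..N")
  if (!identical(sort(object@rois$id), as.integer(ids)))
    return("rois table must have one row per label id")
  tab <- tabulate(lab[lab > 0L], nbins = length(ids))
  if (length(ids) &&
      !all(object@rois$pixel_count[order(object@rois$id)] == tab))
    return("pixel_count must equal mask cardinality per ROI")
  TRUE
})

#' @describeIn RoiLabelMap-class The ROI annotation table.
#' @param x,object A `RoiLabelMap`.
#' @export
setGeneric("roiTable", function(x) standardGeneric("roiTable"))

#' @rdname RoiLabelMap-class
#' @export
setMethod("roiTable", "RoiLabelMap", function(x) x@rois)

#' @describeIn RoiLabelMap-class The integer label matrix.
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname RoiLabelMap-class
#' @export
setMethod("labelMatrix", "RoiLabelMap", function(x) x@labels)

setMethod("show", "RoiLabelMap", function(object) {
  cat(sprintf("RoiLabelMap: %d ROI(s) on a %d x %d raster\n",
              nrow(object@rois), nrow(object@labels), ncol(object@labels)))
  if (nrow(object@rois)) {
    tb <- table(object@rois$kind)
    cat("  ", paste(sprintf("%s: %d", names(tb), tb), collapse = ", "), "\n")
  }
})

#' Calibration model fit with lipid-level covariates
#'
#' Ordinary least squares of per-spot median analyte/IS ratio on deposited
#' amount (ng), with lipid level as a categorical covariate and its
#' interaction with amount (`ratio ~ amount * lipid`). Effect tests for the
#' lipid main effect (intercept) and the lipid x amount interaction (slope)
#' use HC3-studentized Wald statistics calibrated by a null-imposed wild
#' bootstrap (see the methods vignette); classical F tests are available via
#' `fitCalibration(..., testMethod = "classical")`.
#'
#' @slot model The underlying `lm` fit (full interaction model).
#' @slot perLevel `data.frame`: per lipid level intercept, slope, SEs.
#' @slot r2 Global R-squared.
#' @slot tests Named list: `intercept_p`, `slope_p`, `intercept_shift`
#'   (per-level intercept contrasts vs the reference level), `method`.
#' @slot lipidLevels Character vector of level names (reference first).
#' @slot formulaDesc Human-readable model descriptor.
#' @export
setClass("CalibrationFit", representation(
  model = "ANY",
  perLevel = "data.frame",
  r2 = "numeric",
  tests = "list",
  lipidLevels = "character",
  formulaDesc = "character"
))

setValidity("CalibrationFit", function(object) {
  if (!is.na(object@r2) && (object@r2 < 0 || object@r2 > 1))
    return("r2 must lie in [0, 1]")
  need <- c("lipid", "intercept", "slope", "se_intercept", "se_slope")
  if (!all(need %in% names(object@perLevel)))
    return("perLevel must carry intercept/slope and their SEs per level")
  TRUE
})

#' @describeIn CalibrationFit-class Per-lipid-level coefficient table.
#' @param x,object A `CalibrationFit`.
#' @export
setGeneric("calibrationCoefficients",
           function(x) standardGeneric("calibrationCoefficients"))

#' @rdname CalibrationFit-class
#' @export
setMethod("calibrationCoefficients", "CalibrationFit",
          function(x) x@perLevel)

setMethod("show", "CalibrationFit", function(object) {
  cat("CalibrationFit:", object@formulaDesc, "\n")
  cat(sprintf("  R-squared %.4f\n", object@r2))
  print(object@perLevel, row.names = FALSE, digits = 4)
  if (!is.null(object@tests$intercept_p)) {
    cat(sprintf("  lipid effect on intercept: p = %.4g\n",
                object@tests$intercept_p))
    cat(sprintf("  lipid x amount effect on slope: p = %.4g (%s)\n",
                object@tests$slope_p, object@tests$method))
  }
})
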