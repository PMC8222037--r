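# ROI segmentation: tissue sections from the heme B channel (Otsu threshold
# + 3x3 binary closing + 8-connected components + area filter) and
# calibration spots from the tiotropium channel (fixed threshold + area
# band). Annotation matches detected spots to the calibration design layout
# instead of manual labeling.

#' Otsu threshold of a numeric sample
#'
#' Maximizes the between-class variance on a fixed-bin histogram of the
#' finite values (missing pixels excluded). Returns the threshold on the
#' input scale.
#'
#' @param x Numeric vector (NAs dropped).
#' @param nbins Number of histogram bins.
#' @return Threshold value; classifying `x >= threshold` as foreground.
#' @export
otsuThreshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite values to threshold")
  r <- range(x)
  if (diff(r) == 0)
    stop(sprintf("degenerate histogram: all values equal (%.4g)", r[1]))
  br <- seq(r[1], r[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  muT <- mu0[nbins]
  w1 <- 1 - w0
  between <- (muT * w0 - mu0)^2 / (w0 * w1)
  between[!is.finite(between)] <- 0
  # well-separated classes give a plateau of equivalent maxima across the
  # empty gap; take its midpoint (the conventional, most robust cut)
  mx <- max(between)
  ks <- which(between >= mx - 1e-12 * abs(mx))
  k <- ks[ceiling(length(ks) / 2)]
  br[k + 1L]  # boundary above the best background class
}

# 8-connected component labeling of a logical matrix; labels are provisional
# (first-touch order) and re-ordered by .orderRois().
.labelComponents8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  todo <- which(mask)
  nb <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  nextLab <- 0L
  for (seed in todo) {
    if (lab[seed] != 0L) next
    nextLab <- nextLab + 1L
    frontier <- seed
    lab[seed] <- nextLab
    while (length(frontier)) {
      rows <- (frontier - 1L) %% nr + 1L
      cand <- rep(frontier, each = 8L) + nb
      candRow <- rep(rows, each = 8L) + c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
      ok <- cand >= 1L & cand <= nr * nc & candRow >= 1L & candRow <= nr
      cand <- unique(cand[ok])
      cand <- cand[mask[cand] & lab[cand] == 0L]
      lab[cand] <- nextLab
      frontier <- cand
    }
  }
  lab
}

# Relabel components densely, ordered row-major by integer-rounded centroid
# (ties: larger pixel count first), and build the ROI table.
.orderRois <- function(lab, kind) {
  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids)) {
    return(list(labels = lab,
                rois = data.frame(id = integer(0), kind = character(0),
                                  pixel_count = integer(0),
                                  centroid_row = numeric(0),
                                  centroid_col = numeric(0),
                                  annotation = character(0))))
  }
  nr <- nrow(lab)
  pos <- which(lab > 0L)
  lb <- lab[pos]
  row <- (pos - 1L) %% nr + 1L
  col <- (pos - 1L) %/% nr + 1L
  cr <- tapply(row, lb, mean)
  cc <- tapply(col, lb, mean)
  cnt <- tapply(row, lb, length)
  ord <- order(round(cr), round(cc), -cnt)
  remap <- integer(max(ids))
  remap[as.integer(names(cr))[ord]] <- seq_along(ord)
  out <- lab
  out[pos] <- remap[lb]
  list(labels = out,
       rois = data.frame(
         id = seq_along(ord), kind = kind,
         pixel_count = as.integer(cnt[ord]),
         centroid_row = as.numeric(cr[ord]),
         centroid_col = as.numeric(cc[ord]),
         annotation = "", stringsAsFactors = FALSE))
}

.binaryClosing3 <- function(mask) {
  m <- EBImage::closing(mask * 1, EBImage::makeBrush(3L, "box"))
  m > 0
}

#' Segment tissue sections from a heme B ion image
#'
#' Recipe: threshold (Otsu on the histogram of non-missing pixels, or a
#' fixed value), 3x3 binary closing, 8-connected components, drop components
#' below `minAreaPx`, label in row-major centroid order.
#'
#' @param hemeImg Log10-transformed [IonImage-class] of the tissue-marker
#'   (heme B) channel.
#' @param minAreaPx Minimum component area in pixels.
#' @param method `"otsu"` or `"fixed"` (then `threshold` is required).
#' @param threshold Fixed threshold (log10 scale) when `method = "fixed"`.
#' @return A [RoiLabelMap-class] with `kind = "tissue-section"`.
#' @export
segmentTissue <- function(hemeImg, minAreaPx = 20L,
                          method = c("otsu", "fixed"), threshold = NULL) {
  stopifnot(is(hemeImg, "IonImage"))
  method <- match.arg(method)
  if (hemeImg@transform != "log10")
    stop("segmentTissue expects a log10-transformed image")
  if (minAreaPx < 1L) stop("minAreaPx must be >= 1")
  v <- hemeImg@values
  th <- if (method == "otsu") {
    tryCatch(otsuThreshold(as.vector(v)),
             error = function(e)
               stop("no tissue found: ", conditionMessage(e)))
  } else {
    if (is.null(threshold)) stop("method = 'fixed' requires a threshold")
    threshold
  }
  mask <- !is.na(v) & v >= th
  mask <- .binaryClosing3(mask)
  lab <- .labelComponents8(mask)
  keep <- which(tabulate(lab[lab > 0L]) >= minAreaPx)
  lab[!(lab %in% keep)] <- 0L
  if (!any(lab > 0L))
    stop(sprintf("no tissue found (threshold used: %.4g)", th))
  res <- .orderRois(lab, "tissue-section")
  new("RoiLabelMap", labels = res$labels, origin = hemeImg@origin,
      rois = res$rois)
}

#' Detect calibration spots from a tiotropium ion image
#'
#' Pixels at or above `threshold` (log10 scale) form the candidate mask;
#' 8-connected components within `[minAreaPx, maxAreaPx]` become spot ROIs.
#' Raising the threshold never adds a spot. An empty result is returned with
#' a warning, not an error.
#'
#' @param spotImg Log10-transformed [IonImage-class] of the spot-marker
#'   (tiotropium) channel.
#' @param threshold Log10-intensity threshold (default 5.6).
#' @param minAreaPx,maxAreaPx Component area band in pixels.
#' @return A [RoiLabelMap-class] with `kind = "calibration-spot"`.
#' @export
detectSpots <- function(spotImg, threshold = 5.6, minAreaPx = 5L,
                        maxAreaPx = Inf) {
  stopifnot(is(spotImg, "IonImage"))
  if (spotImg@transform != "log10")
    stop("detectSpots expects a log10-transformed image (the threshold is on the log10 scale)")
  v <- spotImg@values
  mask <- !is.na(v) & v >= threshold
  lab <- .labelComponents8(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minAreaPx & sizes <= maxAreaPx)
  lab[!(lab %in% keep)] <- 0L
  if (!any(lab > 0L))
    warning(sprintf("no calibration spots at threshold %.3g", threshold))
  res <- .orderRois(lab, "calibration-spot")
  new("RoiLabelMap", labels = res$labels, origin = spotImg@origin,
      rois = res$rois)
}

#' Annotate detected ROIs from a calibration design
#'
#' Matches each detected calibration-spot ROI to the nearest design position
#' (`row_hint`, `col_hint`, in pixel coordinates of the label map) and
#' attaches the design columns (concentration, drop volume, derived
#' amount_ng, lipid level, replicate). The assignment must be bijective:
#' two spots nearest the same design position is an error naming both, and
#' under `policy = "strict"` every design row must be matched.
#'
#' @param map A [RoiLabelMap-class] with calibration-spot ROIs.
#' @param design `data.frame` with `spot_id`, `row_hint`, `col_hint`,
#'   `conc_ng_per_ul`, `drop_volume_ul`, `lipid_mg_per_g`, `replicate`.
#' @param policy `"strict"` (default: spot count must equal design rows) or
#'   `"partial"` (unmatched design rows are dropped with a warning).
#' @return The map with an annotated ROI table (adds `spot_id`,
#'   `conc_ng_per_ul`, `drop_volume_ul`, `amount_ng`, `lipid_mg_per_g`,
#'   `replicate`).
#' @export
annotateRois <- function(map, design, policy = c("strict", "partial")) {
  stopifnot(is(map, "RoiLabelMap"))
  policy <- match.arg(policy)
  need <- c("spot_id", "row_hint", "col_hint", "conc_ng_per_ul",
            "lipid_mg_per_g", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop("design table misses column(s): ", paste(miss, collapse = ", "))
  if (is.null(design$drop_volume_ul)) design$drop_volume_ul <- 0.5
  design$amount_ng <- design$conc_ng_per_ul * design$drop_volume_ul
  if (any(design$amount_ng < 0)) stop("design amounts must be >= 0")

  rois <- map@rois
  spots <- which(rois$kind == "calibration-spot")
  if (policy == "strict" && length(spots) != nrow(design)) {
    # name the design cell(s) with no spot nearby
    if (length(spots) < nrow(design)) {
      d2 <- vapply(seq_len(nrow(design)), function(k) {
        if (!length(spots)) return(Inf)
        min((rois$centroid_row[spots] - design$row_hint[k])^2 +
            (rois$centroid_col[spots] - design$col_hint[k])^2)
      }, 0)
      farthest <- design$spot_id[order(-d2)[seq_len(nrow(design) -
                                                    length(spots))]]
      stop(sprintf(
        "strict matching: %d spot(s) detected for %d design rows; no spot near design cell(s): %s",
        length(spots), nrow(design), paste(farthest, collapse = ", ")))
    }
    stop(sprintf(
      "strict matching: %d spot(s) detected for %d design rows (extra detections)",
      length(spots), nrow(design)))
  }

  if (length(spots)) {
    nearest <- vapply(spots, function(i) {
      which.min((design$row_hint - rois$centroid_row[i])^2 +
                (design$col_hint - rois$centroid_col[i])^2)
    }, 0L)
    dup <- which(duplicated(nearest) | duplicated(nearest, fromLast = TRUE))
    if (length(dup)) {
      stop(sprintf(
        "ambiguous matching: ROIs %s are all nearest design position '%s'",
        paste(rois$id[spots[dup]], collapse = ", "),
        paste(unique(design$spot_id[nearest[dup]]), collapse = ", ")))
    }
    addCols <- c("spot_id", "conc_ng_per_ul", "drop_volume_ul",
                 "amount_ng", "lipid_mg_per_g", "replicate")
    for (cn in addCols) rois[[cn]] <- NA
    rois[spots, addCols] <- design[nearest, addCols]
    rois$annotation[spots] <- as.character(design$spot_id[nearest])
    if (policy == "partial" && length(spots) < nrow(design))
      warning(sprintf("partial matching: %d of %d design rows unmatched",
                      nrow(design) - length(spots), nrow(design)))
  }
  new("RoiLabelMap", labels = map@labels, origin = map@origin, rois = rois)
}

#' Annotate tissue-section ROIs with slide roles
#'
#' Assigns role labels (e.g. `"sample"`, `"control-2.5ng"`,
#' `"control-10ng"`) to tissue-section ROIs in label order.
#'
#' @param map A [RoiLabelMap-class].
#' @param roles Character vector, one role per tissue-section ROI.
#' @return The annotated map.
#' @export
annotateSections <- function(map, roles) {
  rois <- map@rois
  tis <- which(rois$kind == "tissue-section")
  if (length(tis) != length(roles))
    stop(sprintf("%d tissue section(s) but %d role label(s)",
                 length(tis), length(roles)))
  rois$annotation[tis] <- roles
  new("RoiLabelMap", labels = map@labels, origin = map@origin, rois = rois)
}

#' Export a label map as CSV (one row per labeled pixel)
#'
#' @param map A [RoiLabelMap-class].
#' @param path Output CSV path.
#' @export
writeRoiCSV <- function(map, path) {
  lab <- map@labels
  pos <- which(lab > 0L)
  nr <- nrow(lab)
  df <- data.frame(
    x = (pos - 1L) %/% nr + map@origin[1],
    y = (pos - 1L) %% nr + map@origin[2],
    label = lab[pos])
  write.csv(df[order(df$label, df$y, df$x), ], path, row.names = FALSE)
  invisible(path)
}
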