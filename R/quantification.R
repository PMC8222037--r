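# Internal-standard normalization, per-ROI aggregation, calibration modeling
# with lipid-level covariates (ion-suppression effect tests), inverse
# prediction of deposited amount / tissue concentration, and the spiking
# arithmetic of the homogenate controls.

#' Per-pixel analyte / internal-standard ratio image
#'
#' Ratios are computed on the linear scale: `analyte / IS` where the IS
#' signal is positive; pixels with IS zero or missing are masked (`NA`), and
#' an analyte of 0 with positive IS gives ratio 0. The ratio cancels
#' pixel-to-pixel ionization variability shared by both channels, so jointly
#' rescaling both images leaves every ratio unchanged.
#'
#' @param analyteImg,isImg Linear-scale [IonImage-class]es of identical
#'   shape and origin.
#' @return A linear-scale ratio [IonImage-class].
#' @export
normalizeRatio <- function(analyteImg, isImg) {
  stopifnot(is(analyteImg, "IonImage"), is(isImg, "IonImage"))
  if (analyteImg@transform != "linear" || isImg@transform != "linear")
    stop("normalizeRatio expects linear-scale images")
  if (!identical(dim(analyteImg@values), dim(isImg@values)) ||
      !identical(analyteImg@origin, isImg@origin))
    stop(sprintf("shape mismatch: analyte %s vs IS %s",
                 paste(dim(analyteImg@values), collapse = "x"),
                 paste(dim(isImg@values), collapse = "x")))
  a <- analyteImg@values
  i <- isImg@values
  ratio <- a / i
  masked <- is.na(i) | (!is.na(i) & i == 0)
  ratio[masked] <- NA_real_
  below <- analyteImg@belowDetection | isImg@belowDetection | masked
  new("IonImage", values = ratio, belowDetection = below,
      origin = analyteImg@origin, targetMz = NA_real_,
      tolerance = NA_real_, transform = "linear",
      aggregation = analyteImg@aggregation,
      target = sprintf("%s / %s", analyteImg@target, isImg@target),
      source = analyteImg@source)
}

#' Median / IQR summary of a ratio image per ROI
#'
#' The median and interquartile range are computed over the usable pixels of
#' each ROI (ratio present and positive, i.e. both channels detected);
#' `below_detection_fraction` is the fraction of ROI pixels that are masked
#' or zero. ROIs with no usable pixel are flagged, not dropped. Any
#' annotation columns on the ROI table (amount, lipid level, replicate, ...)
#' are carried through, so the result feeds [fitCalibration()] directly.
#'
#' @param ratioImg A linear-scale ratio [IonImage-class].
#' @param map A [RoiLabelMap-class] of identical shape.
#' @return `data.frame`, one row per ROI.
#' @export
summarizeRoi <- function(ratioImg, map) {
  stopifnot(is(ratioImg, "IonImage"), is(map, "RoiLabelMap"))
  if (!identical(dim(ratioImg@values), dim(map@labels)) ||
      !identical(ratioImg@origin, map@origin))
    stop("shape mismatch between ratio image and label map")
  rois <- map@rois
  out <- lapply(rois$id, function(id) {
    vals <- ratioImg@values[map@labels == id]
    usable <- !is.na(vals) & vals > 0
    data.frame(
      roi_id = id,
      n_pixels_used = sum(usable),
      median_ratio = if (any(usable)) median(vals[usable]) else NA_real_,
      iqr_ratio = if (any(usable))
        diff(quantile(vals[usable], c(0.25, 0.75), names = FALSE))
        else NA_real_,
      below_detection_fraction = mean(!usable),
      flagged = !any(usable))
  })
  out <- do.call(rbind, out)
  extra <- setdiff(names(rois), c("id", "pixel_count"))
  cbind(out, rois[match(out$roi_id, rois$id), extra, drop = FALSE],
        row.names = NULL)
}

# HC3 Wald chi-square statistic for coefficients idx of the model y ~ X.
.hc3Wald <- function(y, X, idx) {
  qrX <- qr(X)
  beta <- qr.coef(qrX, y)
  res <- as.vector(y - X %*% beta)
  h <- rowSums(qr.Q(qrX)^2)
  u <- res / pmax(1 - h, 1e-8)
  XtXinv <- chol2inv(qr.R(qrX))
  V <- XtXinv %*% crossprod(X * u) %*% XtXinv
  b <- beta[idx]
  as.numeric(t(b) %*% solve(V[idx, idx, drop = FALSE], b))
}

# Null-imposed wild (Rademacher) bootstrap p-value for the HC3 Wald test of
# the coefficients idx of the full model X1, with X0 the null design.
.wildBootstrapP <- function(y, X0, X1, idx, B) {
  obs <- .hc3Wald(y, X1, idx)
  f0 <- stats::lm.fit(X0, y)
  fit0 <- f0$fitted.values
  r <- f0$residuals
  n <- length(y)
  stats <- vapply(seq_len(B), function(b) {
    .hc3Wald(fit0 + r * sample(c(-1, 1), n, replace = TRUE), X1, idx)
  }, 0)
  (1 + sum(stats >= obs)) / (B + 1)
}

# Classical nested-F p-value with a guard for (near-)noise-free data: when
# the residual sum of squares is at machine-zero relative to the total, the
# F ratio is 0/0; report p = 1 if the null already fits exactly, p = 0 if
# only the alternative does.
.nestedFP <- function(y, X0, X1) {
  rss <- function(X) sum(stats::lm.fit(X, y)$residuals^2)
  r0 <- rss(X0); r1 <- rss(X1)
  tol <- max(sum((y - mean(y))^2), 1) * 1e-16
  if (r0 <= tol) return(1)
  if (r1 <= tol) return(0)
  df1 <- ncol(X1) - ncol(X0)
  df2 <- length(y) - ncol(X1)
  f <- ((r0 - r1) / df1) / (r1 / df2)
  pf(f, df1, df2, lower.tail = FALSE)
}

#' Fit the calibration model with lipid-level covariates
#'
#' Ordinary least squares of the per-spot median analyte/IS ratio on the
#' deposited amount (ng), with lipid level (mg/g poractant alfa) as a
#' categorical covariate and its interaction with amount:
#' `median_ratio ~ amount_ng * factor(lipid)`. Reports per-level intercepts
#' and slopes, the global R-squared, and two effect tests: (a) lipid main
#' effect on the intercept, (b) lipid x amount interaction on the slope.
#'
#' Because the pixel noise is multiplicative, the residual spread grows with
#' the mean and classical F tests are anticonservative; the default
#' `testMethod = "wild"` therefore calibrates HC3-studentized Wald
#' statistics with a null-imposed wild bootstrap (consumes `2 * B` draws of
#' the RNG). Noise-free data short-circuit deterministically (p = 1 when
#' the null fits exactly, p = 0 when only the alternative does).
#'
#' @param data `data.frame` from [summarizeRoi()] on annotated ROIs, or any
#'   frame with `median_ratio`, `amount_ng`, `lipid_mg_per_g`. Flagged rows
#'   (no usable pixels) are dropped.
#' @param testMethod `"wild"` (default) or `"classical"`.
#' @param B Bootstrap replicates for `testMethod = "wild"`.
#' @return A [CalibrationFit-class].
#' @export
fitCalibration <- function(data, testMethod = c("wild", "classical"),
                           B = 299L) {
  testMethod <- match.arg(testMethod)
  need <- c("median_ratio", "amount_ng", "lipid_mg_per_g")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("calibration data misses column(s): ", paste(miss, collapse = ", "))
  if (!is.null(data$flagged)) data <- data[!data$flagged, , drop = FALSE]
  data <- data[!is.na(data$median_ratio), , drop = FALSE]
  lev <- sort(unique(data$lipid_mg_per_g))
  nAmt <- vapply(lev, function(l)
    length(unique(data$amount_ng[data$lipid_mg_per_g == l])), 0L)
  if (any(nAmt < 2L))
    stop(sprintf(
      "rank-deficient design: lipid level(s) %s have fewer than 2 distinct amounts",
      paste(lev[nAmt < 2L], collapse = ", ")))

  df <- data.frame(ratio = data$median_ratio,
                   amount = data$amount_ng,
                   lipid = factor(data$lipid_mg_per_g, levels = lev))
  singleLevel <- length(lev) == 1L

  if (singleLevel) {
    m <- lm(ratio ~ amount, data = df)
    sm <- suppressWarnings(summary(m))  # exact fits are legitimate here
    perLevel <- data.frame(
      lipid = as.character(lev), intercept = coef(m)[1], slope = coef(m)[2],
      se_intercept = sm$coefficients[1, 2], se_slope = sm$coefficients[2, 2],
      cov_is = suppressWarnings(vcov(m))[1, 2], row.names = NULL)
    return(new("CalibrationFit", model = m, perLevel = perLevel,
               r2 = sm$r.squared,
               tests = list(intercept_p = NA_real_, slope_p = NA_real_,
                            method = "none (single lipid level)"),
               lipidLevels = as.character(lev),
               formulaDesc = "median_ratio ~ amount_ng (single lipid level)"))
  }

  m2 <- lm(ratio ~ amount * lipid, data = df)
  y <- df$ratio
  X0 <- model.matrix(~ amount, df)
  X1 <- model.matrix(~ amount + lipid, df)
  X2 <- model.matrix(~ amount * lipid, df)
  idxInt <- which(colnames(X2) %in% paste0("lipid", lev[-1]))
  idxSlp <- which(colnames(X2) %in% paste0("amount:lipid", lev[-1]))

  tol <- max(sum((y - mean(y))^2), 1) * 1e-16
  rssF <- sum(stats::lm.fit(X2, y)$residuals^2)
  if (testMethod == "classical" || rssF <= tol) {
    pInt <- .nestedFP(y, X0, X2)
    pSlp <- .nestedFP(y, X1, X2)
    method <- if (rssF <= tol) "exact-fit guard" else "classical F"
  } else {
    pInt <- .wildBootstrapP(y, X0, X2, idxInt, B)
    pSlp <- .wildBootstrapP(y, X1, X2, idxSlp, B)
    method <- sprintf("HC3 Wald, wild bootstrap (B = %d)", B)
  }

  # per-level coefficients and their (HC3) covariance
  cf <- coef(m2)
  qr2 <- qr(X2)
  h <- rowSums(qr.Q(qr2)^2)
  u <- m2$residuals / pmax(1 - h, 1e-8)
  XtXinv <- chol2inv(qr.R(qr2))
  Vrob <- XtXinv %*% crossprod(X2 * u) %*% XtXinv
  dimnames(Vrob) <- list(colnames(X2), colnames(X2))
  perLevel <- do.call(rbind, lapply(seq_along(lev), function(k) {
    La <- setNames(numeric(length(cf)), names(cf))
    Lb <- La
    La["(Intercept)"] <- 1
    Lb["amount"] <- 1
    if (k > 1L) {
      La[paste0("lipid", lev[k])] <- 1
      Lb[paste0("amount:lipid", lev[k])] <- 1
    }
    va <- as.numeric(t(La) %*% Vrob %*% La)
    vb <- as.numeric(t(Lb) %*% Vrob %*% Lb)
    cab <- as.numeric(t(La) %*% Vrob %*% Lb)
    data.frame(lipid = as.character(lev[k]),
               intercept = sum(La * cf), slope = sum(Lb * cf),
               se_intercept = sqrt(va), se_slope = sqrt(vb), cov_is = cab)
  }))

  shifts <- data.frame(
    lipid = as.character(lev[-1]),
    estimate = cf[paste0("lipid", lev[-1])],
    se = sqrt(diag(Vrob)[paste0("lipid", lev[-1])]),
    row.names = NULL)
  slopeShifts <- data.frame(
    lipid = as.character(lev[-1]),
    estimate = cf[paste0("amount:lipid", lev[-1])],
    se = sqrt(diag(Vrob)[paste0("amount:lipid", lev[-1])]),
    row.names = NULL)

  new("CalibrationFit", model = m2, perLevel = perLevel,
      r2 = suppressWarnings(summary(m2))$r.squared,
      tests = list(intercept_p = pInt, slope_p = pSlp,
                   intercept_shift = shifts, slope_shift = slopeShifts,
                   method = method),
      lipidLevels = as.character(lev),
      formulaDesc = "median_ratio ~ amount_ng * lipid_level (OLS)")
}

#' Inverse prediction: deposited amount from a measured ratio
#'
#' `amount = (ratio - intercept) / slope` at the requested lipid level, with
#' a first-order (delta-method) interval propagated from the coefficient
#' covariance. Ratios below the intercept give an estimate of 0 with a
#' `below_calibration` flag.
#'
#' @param fit A [CalibrationFit-class].
#' @param ratio Numeric vector of median ratios, or a [summarizeRoi()] frame
#'   (its `median_ratio` column is used).
#' @param lipidLevel Lipid level (matched against the fit's levels; default
#'   the reference level).
#' @param conf Confidence level for the interval.
#' @return `data.frame` with `amount_ng`, `se_amount`, `lower`, `upper`,
#'   `below_calibration`.
#' @export
predictConcentration <- function(fit, ratio, lipidLevel = NULL,
                                 conf = 0.95) {
  stopifnot(is(fit, "CalibrationFit"))
  if (is.data.frame(ratio)) ratio <- ratio$median_ratio
  pl <- fit@perLevel
  lipidLevel <- if (is.null(lipidLevel)) pl$lipid[1] else
    as.character(lipidLevel)
  k <- match(lipidLevel, pl$lipid)
  if (is.na(k))
    stop("lipid level '", lipidLevel, "' not among fitted levels: ",
         paste(pl$lipid, collapse = ", "))
  a <- pl$intercept[k]; b <- pl$slope[k]
  if (b <= 0)
    stop(sprintf("slope at lipid level %s is not positive (%.4g)",
                 lipidLevel, b))
  amount <- (ratio - a) / b
  # delta method on g(a, b) = (r - a)/b
  va <- pl$se_intercept[k]^2; vb <- pl$se_slope[k]^2; cab <- pl$cov_is[k]
  se <- sqrt((va + amount^2 * vb + 2 * amount * cab)) / b
  z <- qnorm(1 - (1 - conf) / 2)
  below <- !is.na(amount) & amount < 0
  est <- pmax(amount, 0)
  data.frame(amount_ng = est, se_amount = se,
             lower = pmax(amount - z * se, 0),
             upper = amount + z * se,
             below_calibration = below)
}

#' Spiking arithmetic for drug/surfactant formulations
#'
#' A volume of drug formulation at a given concentration is mixed into a
#' carrier volume (unit density assumed, so 1 mL weighs 1 g), and the blend
#' is spiked into tissue homogenate at a w/w fraction. Returns the resulting
#' tissue concentration in ug/g; with `spikeFraction = 1` this is the
#' formulation concentration itself.
#'
#' @param volumeA_ul Drug formulation volume (uL).
#' @param concA_mg_per_ml Drug concentration of formulation A (mg/mL).
#' @param volumeB_ul Carrier (e.g. surfactant) volume (uL).
#' @param spikeFraction w/w fraction of the blend in the final homogenate,
#'   in (0, 1].
#' @return Tissue concentration in ug/g.
#' @examples
#' spikeArithmetic(285, 0.25, 714, 0.20)  # ~14.25 ug/g
#' spikeArithmetic(285, 0.25, 714, 0.10)  # ~7.13 ug/g
#' @export
spikeArithmetic <- function(volumeA_ul, concA_mg_per_ml, volumeB_ul,
                            spikeFraction) {
  if (volumeA_ul <= 0 || volumeB_ul < 0) stop("volumes must be positive")
  if (spikeFraction <= 0 || spikeFraction > 1)
    stop("spikeFraction must lie in (0, 1]")
  massUg <- volumeA_ul * concA_mg_per_ml        # uL * mg/mL = ug
  formulation <- massUg / ((volumeA_ul + volumeB_ul) / 1000)  # ug per g
  formulation * spikeFraction
}

#' Per-pixel concentration map inside tissue ROIs
#'
#' Applies the inverse calibration to every tissue pixel of a ratio image:
#' `(ratio - intercept) / slope`, clamped at 0 with a below-detection flag
#' for ratios under the intercept. Background (non-tissue) pixels are
#' masked. Also returns a per-section median/IQR summary table.
#'
#' @param ratioImg Linear-scale ratio [IonImage-class].
#' @param map [RoiLabelMap-class] containing tissue-section ROIs.
#' @param fit A [CalibrationFit-class].
#' @param lipidLevel Lipid level whose calibration line is applied.
#' @return List with `concentration` (an [IonImage-class], units ng per
#'   spot-equivalent of the calibration) and `sections` (a `data.frame`).
#' @export
buildDistributionMap <- function(ratioImg, map, fit, lipidLevel = NULL) {
  stopifnot(is(ratioImg, "IonImage"), is(map, "RoiLabelMap"),
            is(fit, "CalibrationFit"))
  if (!identical(dim(ratioImg@values), dim(map@labels)))
    stop("shape mismatch between ratio image and label map")
  rois <- map@rois
  tis <- rois$id[rois$kind == "tissue-section"]
  if (!length(tis)) stop("no tissue-section ROIs in the label map")
  pl <- fit@perLevel
  lipidLevel <- if (is.null(lipidLevel)) pl$lipid[1] else
    as.character(lipidLevel)
  k <- match(lipidLevel, pl$lipid)
  if (is.na(k)) stop("lipid level not among fitted levels")
  a <- pl$intercept[k]; b <- pl$slope[k]
  if (b <= 0) stop("slope must be positive for inverse prediction")

  conc <- matrix(NA_real_, nrow(ratioImg@values), ncol(ratioImg@values))
  below <- matrix(FALSE, nrow(conc), ncol(conc))
  inTissue <- map@labels %in% tis
  r <- ratioImg@values[inTissue]
  cc <- (r - a) / b
  below[inTissue] <- !is.na(cc) & cc < 0
  cc[!is.na(cc) & cc < 0] <- 0
  conc[inTissue] <- cc

  sections <- do.call(rbind, lapply(tis, function(id) {
    v <- conc[map@labels == id]
    ok <- !is.na(v)
    data.frame(
      roi_id = id,
      annotation = rois$annotation[rois$id == id],
      n_pixels = sum(ok),
      median_concentration = if (any(ok)) median(v[ok]) else NA_real_,
      iqr_concentration = if (any(ok))
        diff(quantile(v[ok], c(0.25, 0.75), names = FALSE)) else NA_real_,
      below_calibration_fraction = mean(below[map@labels == id] | is.na(v)))
  }))

  img <- new("IonImage", values = conc, belowDetection = below,
             origin = ratioImg@origin, targetMz = NA_real_,
             tolerance = NA_real_, transform = "linear",
             aggregation = ratioImg@aggregation,
             target = "concentration", source = ratioImg@source)
  list(concentration = img, sections = sections)
}
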