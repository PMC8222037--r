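# Synthetic centroided MSI slides with the layout of an on-tissue
# calibration experiment: homogenate tissue sections, a dilution series of
# calibration spots (concentrations x replicates x lipid levels), a
# uniformly sprayed internal-standard channel, a heme B channel confined to
# tissue, a tiotropium channel confined to spots, a ferulic-acid matrix
# peak everywhere, and a lipid-dependent additive shift of the calibration
# intercept. Full ground truth is returned next to the spectra, so every
# downstream stage can be tested against known geometry and response.
#
# Noise model: independent multiplicative lognormal noise per pixel per
# channel (sdlog = sigma), ppm-scale m/z jitter on structured peaks, a
# small "chemical background" centroid inside every extraction window, and
# uniform random background peaks. An optional correlated mode reuses the
# internal-standard noise draw for the analyte channel, which the IS
# normalization then cancels exactly.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

.defaultResponse <- function() {
  # baseline analyte/IS ratio (intercept) 1.0, slope 0.05 per ng, intercept
  # shifted up by 10% of the baseline at the 8 mg/g lipid level (5% at
  # 4 mg/g), slopes untouched -- the ion-suppression pattern the pipeline
  # is built to detect. See the methods vignette for the rationale.
  list(intercept = 1.0, slope = 0.05,
       interceptShiftFraction = c(`0` = 0, `4` = 0.05, `8` = 0.10),
       slopeShiftFraction = c(`0` = 0, `4` = 0, `8` = 0))
}

.defaultNoise <- function() {
  list(sigma = 0.10, mzJitterPpm = 2, backgroundRate = 10,
       backgroundIntensity = 0.3, correlated = FALSE)
}

.defaultIntensities <- function() {
  list(is = 1000, heme = 5000, tio = 1e6, fa = 500)
}

.channelMzs <- function() {
  tg <- defaultTargets()
  setNames(tg$mz, tg$role)
}

#' Slide specification for the synthetic calibration experiment
#'
#' One homogenate tissue section per lipid level, each carrying a grid of
#' calibration spots: `length(concentrations)` columns (the dilution
#' series) by `nReplicates` rows. Defaults reproduce the study design:
#' 0.2, 2, 5, 20, 40 ng/uL drops of 500 nL (amounts 0.1-20 ng) in four
#' replicates at lipid levels 0, 4, 8 mg/g.
#'
#' @param lipidLevels Poractant-alfa levels (mg/g), one tissue section each.
#' @param concentrations Dilution series (ng/uL).
#' @param nReplicates Replicates per concentration.
#' @param dropVolumeUl Deposited drop volume (uL).
#' @param spotRadiusPx Spot radius in pixels.
#' @param response,noise,intensities Optional overrides of the response
#'   (intercept/slope/shift fractions), noise and channel base intensities.
#' @param seed RNG seed fixing all randomness of the slide.
#' @return A `SlideSpec` list understood by [generateSlide()].
#' @export
calibrationSlideSpec <- function(lipidLevels = c(0, 4, 8),
                                 concentrations = c(0.2, 2, 5, 20, 40),
                                 nReplicates = 4L, dropVolumeUl = 0.5,
                                 spotRadiusPx = 3L,
                                 response = list(), noise = list(),
                                 intensities = list(), seed = 1L) {
  spacing <- 2L * spotRadiusPx + 2L
  secW <- length(concentrations) * spacing + 4L
  secH <- nReplicates * spacing + 4L
  margin <- 2L; gap <- 4L
  nSec <- length(lipidLevels)
  cols <- 2L * margin + nSec * secW + (nSec - 1L) * gap
  rows <- 2L * margin + secH

  sections <- data.frame(
    section_id = seq_len(nSec),
    role = "control",
    shape = "rect",
    row0 = margin + 1L, row1 = margin + secH,
    col0 = margin + 1L + (seq_len(nSec) - 1L) * (secW + gap),
    spike_ng = 0,
    lipid_mg_per_g = lipidLevels)
  sections$col1 <- sections$col0 + secW - 1L

  spots <- do.call(rbind, lapply(seq_len(nSec), function(s) {
    grid <- expand.grid(rep = seq_len(nReplicates),
                        conc_i = seq_along(concentrations))
    data.frame(
      spot_id = sprintf("L%g-C%g-R%d", lipidLevels[s],
                        concentrations[grid$conc_i], grid$rep),
      center_row = sections$row0[s] + 1L + spotRadiusPx +
        (grid$rep - 1L) * spacing,
      center_col = sections$col0[s] + 1L + spotRadiusPx +
        (grid$conc_i - 1L) * spacing,
      radius_px = spotRadiusPx,
      conc_ng_per_ul = concentrations[grid$conc_i],
      drop_volume_ul = dropVolumeUl,
      lipid_mg_per_g = lipidLevels[s],
      replicate = grid$rep)
  }))

  structure(list(
    dims = c(rows = rows, cols = cols), pixelSizeUm = 400,
    sections = sections, spots = spots,
    response = utils::modifyList(.defaultResponse(), response),
    noise = utils::modifyList(.defaultNoise(), noise),
    intensities = utils::modifyList(.defaultIntensities(), intensities),
    seed = seed), class = c("SlideSpec", "list"))
}

#' Slide specification for the distribution experiment
#'
#' One (elliptical) lung sample section plus two rectangular control
#' homogenate sections spiked with known analyte amounts, emulating a slide
#' of the imaging study. `sampleSpikeNg = 0` gives an untreated slide whose
#' analyte channel contains only chemical background.
#'
#' @param sampleSpikeNg Amount-equivalent driving the sample-section analyte
#'   ratio (ng; 0 = untreated).
#' @param controlSpikesNg Spiked amounts of the two control sections (ng).
#' @param response,noise,intensities Optional overrides, see
#'   [calibrationSlideSpec()].
#' @param seed RNG seed.
#' @return A `SlideSpec` list understood by [generateSlide()].
#' @export
distributionSlideSpec <- function(sampleSpikeNg = 10,
                                  controlSpikesNg = c(2.5, 10),
                                  response = list(), noise = list(),
                                  intensities = list(), seed = 1L) {
  rows <- 28L; margin <- 2L; gap <- 4L
  sections <- data.frame(
    section_id = 1:3,
    role = c(if (sampleSpikeNg > 0) "sample" else "untreated",
             sprintf("control-%gng", controlSpikesNg)),
    shape = c("ellipse", "rect", "rect"),
    row0 = margin + 1L,
    row1 = c(margin + 24L, margin + 20L, margin + 20L),
    col0 = c(margin + 1L, margin + 30L + gap + 1L,
             margin + 30L + gap + 24L + gap + 1L),
    spike_ng = c(sampleSpikeNg, controlSpikesNg),
    lipid_mg_per_g = 0)
  sections$col1 <- sections$col0 + c(30L, 24L, 24L) - 1L
  cols <- sections$col1[3] + margin

  structure(list(
    dims = c(rows = rows, cols = cols), pixelSizeUm = 400,
    sections = sections,
    spots = NULL,
    response = utils::modifyList(.defaultResponse(), response),
    noise = utils::modifyList(.defaultNoise(), noise),
    intensities = utils::modifyList(.defaultIntensities(), intensities),
    seed = seed), class = c("SlideSpec", "list"))
}

.sectionMask <- function(dims, sec) {
  m <- matrix(FALSE, dims["rows"], dims["cols"])
  for (i in seq_len(nrow(sec))) {
    r <- sec$row0[i]:sec$row1[i]
    cl <- sec$col0[i]:sec$col1[i]
    if (sec$shape[i] == "ellipse") {
      cy <- (sec$row0[i] + sec$row1[i]) / 2
      cx <- (sec$col0[i] + sec$col1[i]) / 2
      ry <- (sec$row1[i] - sec$row0[i]) / 2
      rx <- (sec$col1[i] - sec$col0[i]) / 2
      grid <- expand.grid(row = r, col = cl)
      keep <- ((grid$row - cy) / ry)^2 + ((grid$col - cx) / rx)^2 <= 1
      m[cbind(grid$row[keep], grid$col[keep])] <- TRUE
    } else {
      m[r, cl] <- TRUE
    }
  }
  m
}

.sectionLabels <- function(dims, sec) {
  lab <- matrix(0L, dims["rows"], dims["cols"])
  for (i in seq_len(nrow(sec)))
    lab[.sectionMask(dims, sec[i, , drop = FALSE])] <- sec$section_id[i]
  lab
}

.spotLabels <- function(dims, spots) {
  lab <- matrix(0L, dims["rows"], dims["cols"])
  if (is.null(spots) || !nrow(spots)) return(lab)
  for (i in seq_len(nrow(spots))) {
    r0 <- max(1L, spots$center_row[i] - spots$radius_px[i])
    r1 <- min(dims["rows"], spots$center_row[i] + spots$radius_px[i])
    c0 <- max(1L, spots$center_col[i] - spots$radius_px[i])
    c1 <- min(dims["cols"], spots$center_col[i] + spots$radius_px[i])
    grid <- expand.grid(row = r0:r1, col = c0:c1)
    keep <- (grid$row - spots$center_row[i])^2 +
      (grid$col - spots$center_col[i])^2 <= spots$radius_px[i]^2
    cells <- cbind(grid$row[keep], grid$col[keep])
    if (any(lab[cells] != 0L))
      stop("overlapping spot geometry at spot ", spots$spot_id[i])
    lab[cells] <- i
  }
  lab
}

#' Generate a synthetic slide with ground truth
#'
#' Emits a centroided [SpectrumGrid-class] realizing the slide
#' specification, together with the ground truth needed by the tests: true
#' ROI labels, per-pixel analyte amount and expected ratio, the calibration
#' design table (with pixel-coordinate hints for [annotateRois()]) and the
#' response parameters. Identical spec and seed give identical output,
#' down to the imzML bytes written by [writeImzML()].
#'
#' @param spec A `SlideSpec` from [calibrationSlideSpec()] or
#'   [distributionSlideSpec()].
#' @return List with elements `grid` ([SpectrumGrid-class]) and `truth`.
#' @export
generateSlide <- function(spec) {
  stopifnot(inherits(spec, "SlideSpec"))
  dims <- spec$dims
  sec <- spec$sections
  spots <- spec$spots
  noise <- spec$noise
  resp <- spec$response
  ints <- spec$intensities
  if (noise$sigma < 0) stop("noise sigma must be >= 0")
  if (!is.null(spots) && nrow(spots)) {
    if (any(spots$radius_px < 1L)) stop("spot radius must be >= 1 px")
    if (any(spots$center_row - spots$radius_px < 1 |
            spots$center_row + spots$radius_px > dims["rows"] |
            spots$center_col - spots$radius_px < 1 |
            spots$center_col + spots$radius_px > dims["cols"]))
      stop("spot geometry extends beyond the slide")
  }
  if (!is.null(sec) && nrow(sec) &&
      (any(sec$row0 < 1 | sec$col0 < 1 | sec$row1 > dims["rows"] |
           sec$col1 > dims["cols"])))
    stop("section geometry extends beyond the slide")

  mzs <- .channelMzs()
  nPix <- as.integer(dims["rows"]) * as.integer(dims["cols"])

  secLab <- if (!is.null(sec) && nrow(sec)) .sectionLabels(dims, sec)
    else matrix(0L, dims["rows"], dims["cols"])
  spotLab <- .spotLabels(dims, spots)
  tissue <- secLab > 0L
  onSpot <- spotLab > 0L
  sprayed <- tissue | onSpot  # IS + analyte response surface

  # per-pixel truth: lipid level, analyte amount, expected ratio
  lipid <- matrix(0, dims["rows"], dims["cols"])
  amount <- matrix(0, dims["rows"], dims["cols"])
  if (!is.null(sec) && nrow(sec)) {
    for (i in seq_len(nrow(sec))) {
      inSec <- secLab == sec$section_id[i]
      lipid[inSec] <- sec$lipid_mg_per_g[i]
      amount[inSec] <- sec$spike_ng[i]
    }
  }
  design <- NULL
  if (!is.null(spots) && nrow(spots)) {
    design <- data.frame(
      spot_id = spots$spot_id,
      row_hint = spots$center_row, col_hint = spots$center_col,
      conc_ng_per_ul = spots$conc_ng_per_ul,
      drop_volume_ul = spots$drop_volume_ul,
      lipid_mg_per_g = spots$lipid_mg_per_g,
      replicate = spots$replicate)
    design$amount_ng <- design$conc_ng_per_ul * design$drop_volume_ul
    for (i in seq_len(nrow(spots))) {
      inSpot <- spotLab == i
      amount[inSpot] <- design$amount_ng[i]
      lipid[inSpot] <- design$lipid_mg_per_g[i]
    }
  }
  shiftOf <- function(lv) {
    f <- resp$interceptShiftFraction[as.character(lv)]
    ifelse(is.na(f), 0, f) * resp$intercept
  }
  slopeOf <- function(lv) {
    f <- resp$slopeShiftFraction[as.character(lv)]
    resp$slope * (1 + ifelse(is.na(f), 0, f))
  }
  # Expected analyte/IS ratio. Calibration spots always carry the
  # deposition baseline (the calibration intercept); plain tissue carries a
  # structured analyte signal only when spiked -- an unspiked section's
  # analyte window holds nothing but chemical background, so it reads as
  # below-calibration downstream.
  trueRatio <- matrix(0, dims["rows"], dims["cols"])
  withSignal <- onSpot | (tissue & amount > 0)
  trueRatio[withSignal] <- resp$intercept + shiftOf(lipid[withSignal]) +
    slopeOf(lipid[withSignal]) * amount[withSignal]
  if (!is.null(design))
    design$true_ratio <- resp$intercept + shiftOf(design$lipid_mg_per_g) +
      slopeOf(design$lipid_mg_per_g) * design$amount_ng

  grid <- .withSeed(spec$seed, {
    ln <- function(n) if (noise$sigma > 0)
      exp(rnorm(n, 0, noise$sigma)) else rep(1, n)
    jit <- function(mz0, n) if (noise$mzJitterPpm > 0)
      mz0 * (1 + rnorm(n, 0, noise$mzJitterPpm * 1e-6)) else rep(mz0, n)

    pixAll <- seq_len(nPix)
    pixList <- list(); mzList <- list(); intList <- list()
    addPeaks <- function(pix, mzv, intv) {
      k <- length(pixList) + 1L
      pixList[[k]] <<- pix; mzList[[k]] <<- mzv; intList[[k]] <<- intv
    }

    # ferulic-acid matrix peak + in-window chemical background, all pixels
    addPeaks(pixAll, jit(mzs[["lock_mass"]], nPix), ints$fa * ln(nPix))
    for (role in c("analyte", "internal_standard", "spot_marker",
                   "tissue_marker"))
      addPeaks(pixAll, mzs[[role]] + runif(nPix, -0.003, 0.003),
               noise$backgroundIntensity * ln(nPix))

    # structured channels
    spr <- which(sprayed)
    if (length(spr)) {
      isNoise <- ln(length(spr))
      addPeaks(spr, jit(mzs[["internal_standard"]], length(spr)),
               ints$is * isNoise)
      anNoise <- if (isTRUE(noise$correlated)) isNoise else ln(length(spr))
      hasSignal <- trueRatio[spr] > 0
      if (any(hasSignal))
        addPeaks(spr[hasSignal],
                 jit(mzs[["analyte"]], sum(hasSignal)),
                 trueRatio[spr][hasSignal] * ints$is * anNoise[hasSignal])
    }
    tis <- which(tissue)
    if (length(tis))
      addPeaks(tis, jit(mzs[["tissue_marker"]], length(tis)),
               ints$heme * ln(length(tis)))
    spt <- which(onSpot)
    if (length(spt))
      addPeaks(spt, jit(mzs[["spot_marker"]], length(spt)),
               ints$tio * ln(length(spt)))

    # uniform random background peaks
    nBg <- rpois(nPix, noise$backgroundRate)
    if (sum(nBg)) {
      addPeaks(rep.int(pixAll, nBg), runif(sum(nBg), 185, 650),
               noise$backgroundIntensity * ln(sum(nBg)))
    }

    pix <- unlist(pixList); mzv <- unlist(mzList); intv <- unlist(intList)
    ord <- order(pix, mzv)
    pix <- pix[ord]; mzv <- mzv[ord]; intv <- intv[ord]
    f <- factor(pix, levels = pixAll)
    mzSplit <- split(mzv, f)
    intSplit <- split(intv, f)
    # merge exact m/z ties within a pixel (astronomically rare, but the
    # strict-ascending invariant must hold)
    for (i in pixAll) {
      d <- duplicated(mzSplit[[i]])
      if (any(d)) {
        intSplit[[i]] <- as.vector(rowsum(intSplit[[i]],
                                          match(mzSplit[[i]],
                                                unique(mzSplit[[i]]))))
        mzSplit[[i]] <- unique(mzSplit[[i]])
      }
    }
    # pixel linear index i maps to (row, col) = ((i-1) %% rows + 1,
    # (i-1) %/% rows + 1); imzML x = col, y = row
    coords <- cbind(x = (pixAll - 1L) %/% as.integer(dims["rows"]) + 1L,
                    y = (pixAll - 1L) %% as.integer(dims["rows"]) + 1L)
    SpectrumGrid(coords, unname(mzSplit), unname(intSplit),
                 pixelSize = spec$pixelSizeUm, mzRange = c(185, 650),
                 metadata = list(source = sprintf("synthetic-seed-%d",
                                                  spec$seed)))
  })

  list(grid = grid,
       truth = list(sectionLabels = secLab, spotLabels = spotLab,
                    tissueMask = tissue, amount = amount,
                    trueRatio = trueRatio, design = design,
                    sections = sec, response = resp, noise = noise,
                    intensities = ints, channels = mzs, seed = spec$seed))
}

#' Generate a spots-only calibration slide
#'
#' As [generateSlide()] but with the tissue sections removed: only the
#' calibration spots (plus matrix and background peaks) are emitted. With an
#' empty spot list the result is a background-only grid.
#'
#' @param spec A `SlideSpec`; its `sections` are ignored.
#' @return List with `grid` and `truth`, as [generateSlide()].
#' @export
generateCalibrationOnly <- function(spec) {
  stopifnot(inherits(spec, "SlideSpec"))
  spec$sections <- NULL
  generateSlide(spec)
}
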