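# End-to-end orchestration: one config drives simulate -> extract ->
# segment -> normalize -> calibrate -> quantify, with structured one-line
# logging per stage, a manifest (config echo, per-file MD5 checksums) and
# full determinism under a fixed seed.

.configDefaults <- function() {
  list(
    seed = 1L,
    tolerance = 0.005,
    spot_threshold = 5.6,
    aggregation = "sum",
    min_spot_area = 5L,
    max_spot_area = 500L,
    min_tissue_area = 50L,
    test_method = "wild",
    bootstrap_B = 299L,
    lock_mass = NULL,
    input = NULL,
    simulate = list(sample_spike_ng = 10, control_spikes_ng = c(2.5, 10)),
    targets = NULL,
    output_dir = "steroidMSI-run"
  )
}

.checkType <- function(cfg, key, test, what, errors) {
  v <- cfg[[key]]
  if (!is.null(v) && !test(v))
    errors <- c(errors, sprintf("key '%s': expected %s, got %s",
                                key, what, class(v)[1]))
  errors
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path or a named list; fills in the defaults (m/z
#' tolerance 0.005 Da, spot threshold 5.6 on the log10 scale, sum
#' aggregation, seed 1) and type-checks every provided key. All problems
#' are reported together, each naming the offending key.
#'
#' @param config Path to a YAML config or a named list.
#' @param strict Reject unknown keys (default `TRUE`).
#' @return The normalized config list (class `RunConfig`).
#' @export
validateConfig <- function(config, strict = TRUE) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  defaults <- .configDefaults()
  errors <- character(0)
  if (strict) {
    unknown <- setdiff(names(config), names(defaults))
    if (length(unknown))
      errors <- c(errors, sprintf("unknown key '%s'", unknown))
  }
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  int1 <- function(v) num1(v) && v == round(v)
  chr1 <- function(v) is.character(v) && length(v) == 1L
  errors <- .checkType(config, "seed", int1, "an integer", errors)
  errors <- .checkType(config, "tolerance", num1, "a number", errors)
  errors <- .checkType(config, "spot_threshold", num1, "a number", errors)
  errors <- .checkType(config, "aggregation",
                       function(v) chr1(v) && v %in% c("sum", "max"),
                       "'sum' or 'max'", errors)
  errors <- .checkType(config, "min_spot_area", int1, "an integer", errors)
  errors <- .checkType(config, "max_spot_area", num1, "a number", errors)
  errors <- .checkType(config, "min_tissue_area", int1, "an integer",
                       errors)
  errors <- .checkType(config, "test_method",
                       function(v) chr1(v) && v %in% c("wild", "classical"),
                       "'wild' or 'classical'", errors)
  errors <- .checkType(config, "bootstrap_B", int1, "an integer", errors)
  errors <- .checkType(config, "output_dir", chr1, "a path string", errors)
  if (!is.null(config$tolerance) && is.numeric(config$tolerance) &&
      config$tolerance <= 0)
    errors <- c(errors, "key 'tolerance': must be > 0")
  if (!is.null(config$lock_mass) && !is.list(config$lock_mass))
    errors <- c(errors, "key 'lock_mass': expected a map (mz, window, mode)")
  if (!is.null(config$input)) {
    if (!is.list(config$input)) {
      errors <- c(errors, "key 'input': expected a map with 'calibration', 'distribution', 'design'")
    } else {
      for (k in c("calibration", "distribution", "design"))
        if (is.null(config$input[[k]]))
          errors <- c(errors, sprintf("key 'input.%s': required when input is given", k))
    }
  }
  if (length(errors))
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  out <- utils::modifyList(defaults, config, keep.null = TRUE)
  out$seed <- as.integer(out$seed)
  structure(out, class = c("RunConfig", "list"))
}

#' Write a configuration to YAML
#'
#' `validateConfig(writeConfig(cfg, path))` round-trips losslessly:
#' normalizing an already-normalized config is the identity.
#'
#' @param config A config list (validated or not).
#' @param path Output YAML path.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(unclass(config)[!vapply(unclass(config), is.null, TRUE)],
                   path)
  invisible(path)
}

.stageLog <- function(name, ...) {
  message(sprintf("[%s] %s", name, sprintf(...)))
}

.extractChannels <- function(grid, targets, tolerance, aggregation) {
  imgs <- lapply(seq_len(nrow(targets)), function(i)
    extractIonImage(grid, targets$mz[i], tolerance = tolerance,
                    aggregation = aggregation, target = targets$name[i]))
  names(imgs) <- targets$role
  imgs
}

#' Run the full quantitative MSI pipeline
#'
#' Stages: `simulate` (or load the configured imzML inputs), `extract`
#' (ion images for analyte, internal standard, spot and tissue markers),
#' `segment` (tissue sections via Otsu on the tissue marker; calibration
#' spots via the fixed threshold on the spot marker; design-driven
#' annotation), `normalize` (analyte/IS ratio images), `calibrate` (per-spot
#' summaries, calibration fit with lipid-effect tests), `quantify`
#' (concentration map and per-section summaries). All outputs land under
#' `output_dir` together with `manifest.json` (stage status, parameters and
#' MD5 checksum of every file). Rerunning with the same config and seed
#' reproduces every output byte-for-byte.
#'
#' @param config A config list or YAML path, see [validateConfig()].
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
  cfg <- validateConfig(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "steroidMSI",
                   version = as.character(utils::packageVersion("steroidMSI")),
                   config = unclass(cfg)[!vapply(unclass(cfg), is.null,
                                                 TRUE)],
                   stages = list(), files = list())
  state <- new.env(parent = emptyenv())
  outFile <- function(...) file.path(cfg$output_dir, ...)

  finishManifest <- function(failed = NULL) {
    if (!is.null(failed)) manifest$failed <- failed
    fl <- list.files(cfg$output_dir, recursive = TRUE, full.names = TRUE)
    fl <- fl[basename(fl) != "manifest.json"]
    manifest$files <- lapply(fl, function(f)
      list(path = sub(paste0("^", cfg$output_dir, "/?"), "", f),
           md5 = unname(tools::md5sum(f))))
    jsonlite::write_json(manifest, outFile("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    manifest
  }

  runStage <- function(name, params, fun) {
    .stageLog(name, "%s", paste(names(params), unlist(params), sep = "=",
                                collapse = " "))
    res <- tryCatch(fun(), error = function(e) e)
    ok <- !inherits(res, "error")
    manifest$stages[[length(manifest$stages) + 1L]] <<- list(
      name = name, status = if (ok) "ok" else "failed", params = params)
    if (!ok) {
      manifest <<- finishManifest(failed = name)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(res)), call. = FALSE)
    }
    res
  }

  targets <- if (is.null(cfg$targets)) defaultTargets() else
    readTargetTable(cfg$targets)

  # -- 1. simulate (or load) -------------------------------------------------
  runStage("simulate", list(seed = cfg$seed,
                            source = if (is.null(cfg$input)) "synthetic"
                                     else "files"), function() {
    if (is.null(cfg$input)) {
      cal <- generateSlide(calibrationSlideSpec(seed = cfg$seed))
      dst <- generateSlide(distributionSlideSpec(
        sampleSpikeNg = cfg$simulate$sample_spike_ng,
        controlSpikesNg = cfg$simulate$control_spikes_ng,
        seed = cfg$seed + 1L))
      dir.create(outFile("simulated"), showWarnings = FALSE)
      writeImzML(cal$grid, outFile("simulated", "calibration.imzML"))
      writeImzML(dst$grid, outFile("simulated", "distribution.imzML"))
      write.csv(cal$truth$design, outFile("simulated", "design.csv"),
                row.names = FALSE)
      state$design <- cal$truth$design
      state$sections <- dst$truth$sections
      state$cal <- readImzML(outFile("simulated", "calibration.imzML"))
      state$dist <- readImzML(outFile("simulated", "distribution.imzML"))
    } else {
      state$cal <- readImzML(cfg$input$calibration)
      state$dist <- readImzML(cfg$input$distribution)
      state$design <- read.csv(cfg$input$design)
      state$roles <- cfg$input$section_roles
    }
    invisible(TRUE)
  })

  # -- 2. extract ------------------------------------------------------------
  runStage("extract", list(tolerance = cfg$tolerance,
                           aggregation = cfg$aggregation), function() {
    if (!is.null(cfg$lock_mass)) {
      state$cal <- lockMassRecalibrate(
        state$cal, lockMz = cfg$lock_mass$mz %||% 195.0657,
        searchWindow = cfg$lock_mass$window %||% 0.01,
        mode = cfg$lock_mass$mode %||% "ppm")
      state$dist <- lockMassRecalibrate(
        state$dist, lockMz = cfg$lock_mass$mz %||% 195.0657,
        searchWindow = cfg$lock_mass$window %||% 0.01,
        mode = cfg$lock_mass$mode %||% "ppm")
    }
    state$calImgs <- .extractChannels(state$cal, targets, cfg$tolerance,
                                      cfg$aggregation)
    state$distImgs <- .extractChannels(state$dist, targets, cfg$tolerance,
                                       cfg$aggregation)
    dir.create(outFile("images"), showWarnings = FALSE)
    for (role in names(state$distImgs))
      writeIonImageCSV(state$distImgs[[role]],
                       outFile("images", paste0("distribution-", role,
                                                ".csv")))
    invisible(TRUE)
  })

  # -- 3. segment ------------------------------------------------------------
  runStage("segment", list(spot_threshold = cfg$spot_threshold,
                           min_tissue_area = cfg$min_tissue_area),
           function() {
    spotMap <- detectSpots(
      logTransform(state$calImgs$spot_marker),
      threshold = cfg$spot_threshold, minAreaPx = cfg$min_spot_area,
      maxAreaPx = cfg$max_spot_area)
    state$spotMap <- annotateRois(spotMap, state$design)
    tisMap <- segmentTissue(logTransform(state$distImgs$tissue_marker),
                            minAreaPx = cfg$min_tissue_area)
    # role labels: match each detected section to the nearest design/truth
    # section center (ROI label order is centroid-sorted, not design order)
    roles <- NULL
    if (!is.null(state$sections)) {
      sec <- state$sections
      rt <- roiTable(tisMap)
      cy <- (sec$row0 + sec$row1) / 2
      cx <- (sec$col0 + sec$col1) / 2
      roles <- vapply(seq_len(nrow(rt)), function(i)
        sec$role[which.min((cy - rt$centroid_row[i])^2 +
                           (cx - rt$centroid_col[i])^2)], "")
    } else if (!is.null(state$roles) &&
               length(state$roles) == nrow(roiTable(tisMap))) {
      roles <- state$roles
    }
    state$tisMap <- if (!is.null(roles)) annotateSections(tisMap, roles)
      else tisMap
    dir.create(outFile("rois"), showWarnings = FALSE)
    writeRoiCSV(state$spotMap, outFile("rois", "calibration-spots.csv"))
    writeRoiCSV(state$tisMap, outFile("rois", "tissue-sections.csv"))
    invisible(TRUE)
  })

  # -- 4. normalize ----------------------------------------------------------
  runStage("normalize", list(), function() {
    state$calRatio <- normalizeRatio(state$calImgs$analyte,
                                     state$calImgs$internal_standard)
    state$distRatio <- normalizeRatio(state$distImgs$analyte,
                                      state$distImgs$internal_standard)
    writeIonImageCSV(state$distRatio, outFile("images",
                                              "distribution-ratio.csv"))
    invisible(TRUE)
  })

  # -- 5. calibrate ----------------------------------------------------------
  runStage("calibrate", list(test_method = cfg$test_method,
                             B = cfg$bootstrap_B), function() {
    summaries <- summarizeRoi(state$calRatio, state$spotMap)
    write.csv(summaries, outFile("calibration-summaries.csv"),
              row.names = FALSE)
    set.seed(cfg$seed)  # bootstrap draws
    fit <- fitCalibration(summaries, testMethod = cfg$test_method,
                          B = cfg$bootstrap_B)
    state$fit <- fit
    jsonlite::write_json(list(
      formula = fit@formulaDesc,
      r_squared = fit@r2,
      per_level = calibrationCoefficients(fit),
      intercept_effect_p = fit@tests$intercept_p,
      slope_effect_p = fit@tests$slope_p,
      intercept_shift = fit@tests$intercept_shift,
      test_method = fit@tests$method),
      outFile("calibration-fit.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
    invisible(TRUE)
  })

  # -- 6. quantify -----------------------------------------------------------
  runStage("quantify", list(lipid_level = "0"), function() {
    dm <- buildDistributionMap(state$distRatio, state$tisMap, state$fit,
                               lipidLevel = "0")
    writeIonImageCSV(dm$concentration, outFile("concentration-map.csv"))
    write.csv(dm$sections, outFile("section-summaries.csv"),
              row.names = FALSE)
    invisible(TRUE)
  })

  invisible(finishManifest())
}
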