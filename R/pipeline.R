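# End-to-end orchestration: simulate -> preprocess -> stitch -> segment ->
# quantify -> stats as one reproducible run driven by a validated config
# with a single root seed expanded into named per-stage substreams.

#' Default pipeline configuration
#'
#' Reproduces the study design: 5 slides per grade, 2 stitched mosaics
#' per slide and 5 analysis windows per mosaic (10 windows per section),
#' 13 bands over 420-680 nm (see [defaultBandCenters()]), 0.5 um/px,
#' 5 frames per field.
#'
#' @param seed Root seed; all stage seeds derive from it.
#' @return Nested configuration list (see [validateRunConfig()]).
#' @export
defaultRunConfig <- function(seed = 0L) {
  list(
    seed = as.integer(seed),
    pixelSize = 0.5,
    bitDepth = 8L,
    bands = defaultBandCenters(),
    design = list(nSlidesPerGrade = 5L, mosaicsPerSlide = 2L,
                  tilesPerMosaic = 2L, tileSize = 600L,
                  overlapFraction = 0.3, windowsPerMosaic = 5L),
    window = list(size = 200L, stride = 50L, exposure = c(0.1, 0.9),
                  centralFrac = 0.5, maxPearlFrac = 0.05),
    segmentation = list(blockSize = 51L, offsetFrac = 0.02, minArea = 30L,
                        probThreshold = 0.5, minNucleusArea = 30L,
                        minPitArea = 200L, nTrees = 100L, maxDepth = 12L,
                        maxPerClass = 50000L),
    quantify = list(ratioMode = "cyto", minPearlAreaUm2 = 100,
                    atypiaThresholds = c(10, 20, 30, 40)),
    grades = list(normal = gradeParams("normal"),
                  poorly = gradeParams("poorly"),
                  well = gradeParams("well"))
  )
}

#' Validate a pipeline configuration against the expected schema
#' @param config Configuration list (see [defaultRunConfig()]).
#' @return The config, invisibly, or an error naming the offending field.
#' @export
validateRunConfig <- function(config) {
  need <- c("seed", "pixelSize", "bitDepth", "bands", "design", "window",
            "segmentation", "quantify", "grades")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop(sprintf("config is missing field(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  .assertScalarNumeric(config$pixelSize, "pixelSize", positive = TRUE)
  if (length(config$bands) < 2L || any(diff(config$bands) <= 0))
    stop("config$bands must be >= 2 strictly increasing wavelengths",
         call. = FALSE)
  d <- config$design
  for (f in c("nSlidesPerGrade", "mosaicsPerSlide", "tilesPerMosaic",
              "tileSize", "windowsPerMosaic"))
    if (is.null(d[[f]]) || d[[f]] < 1)
      stop(sprintf("config$design$%s must be >= 1", f), call. = FALSE)
  if (d$overlapFraction < 0.15 || d$overlapFraction > 0.6)
    stop("config$design$overlapFraction must be within [0.15, 0.6]",
         call. = FALSE)
  if (config$window$size > d$tileSize)
    stop("analysis window larger than tile", call. = FALSE)
  if (!all(c("normal", "poorly", "well") %in% names(config$grades)))
    stop("config$grades must define normal, poorly and well", call. = FALSE)
  invisible(config)
}

#' Simulate, preprocess and annotate phantom fields of one grade
#'
#' Convenience generator used for validation studies: samples a scene,
#' renders the configured number of noisy frames, averages them and
#' corrects illumination, and returns the preprocessed stack together
#' with the scene and its ground truth.
#'
#' @param grade Tissue grade.
#' @param nFields Number of fields.
#' @param fieldShape Field size in px.
#' @param params Generator parameters (default `gradeParams(grade)`).
#' @param bands Band centers in nm.
#' @param pixelSize Pixel size in um/px.
#' @param seed Root seed; fields get independent substreams.
#' @param correct Apply illumination correction.
#' @return List of `list(stack, truth, scene)` per field.
#' @export
simulateFields <- function(grade, nFields, fieldShape = c(600L, 600L),
                           params = gradeParams(grade),
                           bands = defaultBandCenters(), pixelSize = 0.5,
                           seed = 1L, correct = TRUE) {
  spectra <- makeStainSpectra(bands)
  lapply(seq_len(nFields), function(i) {
    sSeed <- splitSeed(seed, sprintf("field_%s_%03d_scene", grade, i))
    nSeed <- splitSeed(seed, sprintf("field_%s_%03d_noise", grade, i))
    scene <- sampleScene(grade, params, fieldShape, pixelSize, seed = sSeed)
    frames <- renderStack(scene, spectra,
                          vignetteStrength = params$illumVignetteStrength,
                          noiseSigma = params$noiseSigma,
                          nFrames = params$framesPerField, seed = nSeed,
                          fieldId = sprintf("%s_%03d", grade, i))
    list(stack = preprocessField(frames, correct = correct),
         truth = scene@truthMask, scene = scene)
  })
}

#' Train the nucleus classifier on dedicated phantom training fields
#'
#' One annotated field per grade is simulated under an independent seed
#' substream and used to fit the random-forest pixel classifier, so
#' evaluation fields are never part of training.
#'
#' @param config Pipeline configuration.
#' @return A [NucleusModel-class].
#' @export
trainPipelineModel <- function(config = defaultRunConfig()) {
  validateRunConfig(config)
  fields <- lapply(names(config$grades), function(g) {
    simulateFields(g, 1L, fieldShape = c(600L, 600L),
                   params = config$grades[[g]], bands = config$bands,
                   pixelSize = config$pixelSize,
                   seed = splitSeed(config$seed, paste0("train_", g)))[[1L]]
  })
  sg <- config$segmentation
  trainNucleusRF(lapply(fields, `[[`, "stack"),
                 lapply(fields, `[[`, "truth"),
                 nTrees = sg$nTrees, maxDepth = sg$maxDepth,
                 maxPerClass = sg$maxPerClass,
                 seed = splitSeed(config$seed, "train_rf"))
}

.writeRGB <- function(rgb, path) {
  png::writePNG(aperm(rgb, c(1, 2, 3)), path)
  invisible(path)
}

#' Run the full staging pipeline on simulated slides
#'
#' For every grade, slide and mosaic: samples a wide phantom scene, cuts
#' it into an overlapping tile strip with per-tile frames, averages
#' frames and corrects illumination, stitches the tiles on the 630 nm
#' band, segments all classes, composes pseudo-color and atypia overlays,
#' selects quality-controlled windows, and accumulates the measurement
#' table (window nucleo/cytoplasmic ratios; per-mosaic atypia fractions
#' and keratin-pearl counts).  Grade-comparison statistics and ROC curves
#' are written to `report/`.  Reruns with the same config produce
#' byte-identical CSV outputs.
#'
#' @param config Configuration list from [defaultRunConfig()].
#' @param outDir Output directory (created; layout: `mosaics/`, `masks/`,
#'   `pseudocolor/`, `overlays/`, `measurements.csv`, `report/`,
#'   `manifest.json`).
#' @param model Optional pre-trained [NucleusModel-class]; default trains
#'   one with [trainPipelineModel()].
#' @param verbose Emit per-stage progress messages.
#' @return List with `measurements` (data.frame), `reports` (per metric),
#'   and `outDir`.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir,
                        model = NULL, verbose = TRUE) {
  validateRunConfig(config)
  say <- function(...) if (verbose) message(sprintf(...))
  for (sub in c("", "mosaics", "masks", "pseudocolor", "overlays", "report"))
    dir.create(file.path(outDir, sub), recursive = TRUE, showWarnings = FALSE)
  spectra <- makeStainSpectra(config$bands)
  if (is.null(model)) {
    say("training nucleus classifier on dedicated phantom fields ...")
    model <- trainPipelineModel(config)
  }
  d <- config$design; sg <- config$segmentation
  wcfg <- config$window; qcfg <- config$quantify
  step <- round((1 - d$overlapFraction) * d$tileSize)
  sceneW <- (d$tilesPerMosaic - 1L) * step + d$tileSize
  rows <- list()
  for (grade in names(config$grades)) {
    params <- config$grades[[grade]]
    for (s in seq_len(d$nSlidesPerGrade)) {
      slideId <- sprintf("%s_slide%02d", grade, s)
      for (m in seq_len(d$mosaicsPerSlide)) {
        tag <- sprintf("%s_m%d", slideId, m)
        scene <- sampleScene(grade, params,
                             fieldShape = c(d$tileSize, sceneW),
                             pixelSize = config$pixelSize,
                             seed = splitSeed(config$seed, paste0("scene_", tag)))
        tiles <- makeTileset(scene, spectra, nTiles = d$tilesPerMosaic,
                             overlapFraction = d$overlapFraction,
                             tileWidth = d$tileSize,
                             vignetteStrength = params$illumVignetteStrength,
                             noiseSigma = params$noiseSigma,
                             nFrames = params$framesPerField,
                             seed = splitSeed(config$seed, paste0("noise_", tag)),
                             bitDepth = config$bitDepth)
        tilesPre <- lapply(tiles, function(t) preprocessField(t$frames))
        st <- stitchStrip(tilesPre, refWavelength = 630,
                          seed = splitSeed(config$seed, paste0("ransac_", tag)))
        mosaic <- st$mosaic
        mask <- segmentField(mosaic, model, grade,
                             blockSize = sg$blockSize,
                             offsetFrac = sg$offsetFrac,
                             minArea = sg$minArea,
                             probThreshold = sg$probThreshold,
                             minNucleusArea = sg$minNucleusArea,
                             minPitArea = sg$minPitArea)
        writeStack(mosaic, file.path(outDir, "mosaics", paste0(tag, ".tif")))
        writeMask(mask, file.path(outDir, "masks", paste0(tag, ".png")))
        .writeRGB(composePseudocolor(mask, grade),
                  file.path(outDir, "pseudocolor", paste0(tag, ".png")))

        wins <- selectWindows(mosaic, mask, grade = grade,
                              nWindows = d$windowsPerMosaic,
                              window = wcfg$size, stride = wcfg$stride,
                              exposure = wcfg$exposure,
                              centralFrac = wcfg$centralFrac,
                              maxPearlFrac = wcfg$maxPearlFrac)
        lab <- labels2d(mask)
        nucAll <- classLayer(mask, "nucleus")
        tissueAll <- lab != classCodes(mask)[["background"]]
        for (wI in seq_len(nrow(wins))) {
          rr <- wins$row0[wI]:(wins$row0[wI] + wins$size[wI] - 1L)
          cc <- wins$col0[wI]:(wins$col0[wI] + wins$size[wI] - 1L)
          nc <- ncRatio(nucAll[rr, cc], tissueAll[rr, cc],
                        mode = qcfg$ratioMode)
          rows[[length(rows) + 1L]] <- data.frame(
            slide_id = slideId,
            field_or_window_id = sprintf("m%d_w%d", m, wI),
            grade_label = grade, metric_name = "nc_ratio", value = nc)
        }
        inst <- splitInstances(nucAll)
        areas <- nucleusAreas(inst, config$pixelSize)
        if (nrow(areas) > 0L) {
          fb <- fractionBelow(areas, qcfg$atypiaThresholds)
          for (t in names(fb$fractions)) {
            rows[[length(rows) + 1L]] <- data.frame(
              slide_id = slideId, field_or_window_id = sprintf("m%d", m),
              grade_label = grade,
              metric_name = paste0("fraction_below_", t),
              value = fb$fractions[[t]])
          }
          .writeRGB(atypiaOverlay(inst, config$pixelSize),
                    file.path(outDir, "overlays", paste0(tag, ".png")))
        }
        if (grade != "normal") {
          pInst <- splitInstances(classLayer(mask, "bright600"),
                                  classOf = classCodes(mask)[["bright600"]])
          ps <- keratinPearlStats(pInst, config$pixelSize,
                                  qcfg$minPearlAreaUm2)
          rows[[length(rows) + 1L]] <- data.frame(
            slide_id = slideId, field_or_window_id = sprintf("m%d", m),
            grade_label = grade, metric_name = "pearl_count",
            value = ps$count)
          rows[[length(rows) + 1L]] <- data.frame(
            slide_id = slideId, field_or_window_id = sprintf("m%d", m),
            grade_label = grade, metric_name = "pearl_total_area_um2",
            value = ps$total_um2)
        }
        say("%s: %d windows, %d nuclei, mosaic %d x %d",
            tag, nrow(wins), nrow(areas), dim(mosaic)[1L], dim(mosaic)[2L])
      }
    }
  }
  measurements <- do.call(rbind, rows)
  writeMeasurements(measurements, file.path(outDir, "measurements.csv"))

  reports <- list()
  for (metric in c("nc_ratio", "fraction_below_20", "pearl_count")) {
    if (!any(measurements$metric_name == metric)) next
    rep <- suppressWarnings(
      gradeComparisonReport(measurements, metric,
                            pooledTumor = metric == "nc_ratio"))
    reports[[metric]] <- rep
    if (nrow(rep$summary)) {
      utils::write.csv(rep$summary,
                       file.path(outDir, "report",
                                 paste0("comparison_", metric, ".csv")),
                       row.names = FALSE)
      for (nm in setdiff(names(rep), "summary")) {
        roc <- rep[[nm]]$roc
        utils::write.csv(data.frame(fpr = roc$fpr, tpr = roc$tpr),
                         file.path(outDir, "report",
                                   sprintf("roc_%s_%s.csv", metric, nm)),
                         row.names = FALSE)
        grDevices::png(file.path(outDir, "report",
                                 sprintf("roc_%s_%s.png", metric, nm)),
                       width = 480, height = 480)
        plot(roc$fpr, roc$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
             xlab = "False positive rate", ylab = "True positive rate",
             main = sprintf("%s / %s (AUC %.3f)", metric, nm, roc$auc))
        graphics::abline(0, 1, lty = 2, col = "gray")
        grDevices::dev.off()
      }
    }
  }
  cfgJson <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(package = as.character(utils::packageVersion("msiStage")),
         seed = config$seed,
         config_hash = sum(utf8ToInt(cfgJson)) %% 1000000007,
         config = config),
    file.path(outDir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  list(measurements = measurements, reports = reports, outDir = outDir,
       model = model)
}
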