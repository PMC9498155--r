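#' @include AllClasses.R synthetic.R patching.R classifier.R segmentation.R
#' @include evaluation.R optimization.R
NULL

pipelineDefaults <- function() {
  list(
    synth = list(nSlides = 10L, masterSeed = 7L, height = 896L,
                 width = 1280L, nTumorRegions = 2L, nNormalRegions = 2L,
                 regionSizeRange = c(288L, 384L), minSeparation = 132L),
    tileSize = 128L,
    stride = 128L,
    downsampleFactors = 1L,
    whitenessThreshold = 220,
    fractions = c(0.70, 0.10, 0.20),
    seeds = list(split = 11L, balance = 12L, init = 13L, train = 14L),
    classifier = list(),
    sweepGridStep = 0.01,
    segmentStep = 32L,
    stepList = c(128L, 64L, 32L, 16L, 8L),
    runTradeoff = FALSE,
    threshold = NULL
  )
}

mergeConfig <- function(base, override, path = "") {
  for (nm in names(override)) {
    if (!nm %in% names(base))
      stop(sprintf("unknown config key '%s%s'", path, nm))
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      base[[nm]] <- mergeConfig(base[[nm]], as.list(override[[nm]]),
                                paste0(path, nm, "."))
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

validatePipelineConfig <- function(config) {
  if (config$stride > config$tileSize)
    stop("stride must not exceed tileSize (tiles would skip annotated area)")
  if (any(config$downsampleFactors < 1))
    stop("downsampleFactors must be >= 1")
  if (length(config$fractions) != 3L ||
      abs(sum(config$fractions) - 1) > 1e-8)
    stop("fractions must be three numbers summing to 1")
  if (!config$segmentStep %in% 1:config$tileSize)
    stop("segmentStep must lie in [1, tileSize]")
  if (config$sweepGridStep <= 0 || config$sweepGridStep > 1)
    stop("sweepGridStep must lie in (0, 1]")
  invisible(config)
}

#' Read and validate a pipeline configuration
#'
#' Loads a YAML file, overlays it on the package defaults and rejects
#' unknown keys; every numeric field is validated. With `path = NULL` the
#' defaults themselves are returned.
#'
#' @param path YAML file path or `NULL`.
#' @return named configuration list.
#' @export
readPipelineConfig <- function(path = NULL) {
  config <- pipelineDefaults()
  if (!is.null(path))
    config <- mergeConfig(config, yaml::read_yaml(path))
  validatePipelineConfig(config)
  config
}

configHash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

stageMarker <- function(outDir, stage) file.path(outDir, paste0(stage, ".done"))

stageDone <- function(outDir, stage, hash) {
  mk <- stageMarker(outDir, stage)
  if (!file.exists(mk)) return(FALSE)
  seen <- readLines(mk, warn = FALSE)[1]
  if (!identical(seen, hash))
    stop(sprintf(
      "artifacts in '%s' were produced under a different config (stage %s); refusing to mix",
      outDir, stage))
  TRUE
}

finishStage <- function(outDir, stage, hash)
  writeLines(hash, stageMarker(outDir, stage))

requireStage <- function(outDir, stage, file) {
  if (!file.exists(file))
    stop(sprintf("missing artifact '%s'; rerun stage '%s'", file, stage))
  file
}

#' Run the full segmentation pipeline on a synthetic cohort
#'
#' Executes the stages in order — synth, extract, train, sweep, segment,
#' evaluate — writing artifacts under `outDir`. Each stage is idempotent:
#' on rerun, finished stages are skipped as long as the configuration hash
#' matches (a differing hash is refused rather than silently mixed). The
#' stage flow is: generate the annotated cohort; rasterize annotations and
#' cut balanced, by-slide-split tile datasets; train the patch classifier
#' with early stopping; sweep the decision threshold on validation patches;
#' segment the test slides at the configured step with the selected
#' threshold; report kernel-level and pixel-level metrics.
#'
#' @param config configuration list from [readPipelineConfig()].
#' @param outDir artifacts directory.
#' @param quiet suppress progress messages.
#' @return (invisibly) list with the trained model, sweep result, kernel
#'   metrics report, per-slide pixel reports and their macro-average.
#' @export
runPipeline <- function(config = readPipelineConfig(), outDir, quiet = FALSE) {
  validatePipelineConfig(config)
  hash <- configHash(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(outDir, "config.yaml"))
  say <- function(...) if (!quiet) message(sprintf(...))

  # --- synth ---------------------------------------------------------------
  cohortDir <- file.path(outDir, "cohort")
  if (!stageDone(outDir, "synth", hash)) {
    say("stage synth: generating %d slides", config$synth$nSlides)
    spec <- syntheticSlideSpec(
      height = config$synth$height, width = config$synth$width,
      nTumorRegions = config$synth$nTumorRegions,
      nNormalRegions = config$synth$nNormalRegions,
      regionSizeRange = config$synth$regionSizeRange,
      minSeparation = config$synth$minSeparation)
    cohort <- generateCohort(config$synth$nSlides, spec,
                             config$synth$masterSeed)
    dir.create(cohortDir, showWarnings = FALSE)
    for (entry in cohort) {
      id <- slideId(entry$slide)
      writeSlide(entry$slide, file.path(cohortDir, paste0(id, ".png")))
      writeAnnotations(entry$annotations,
                       file.path(cohortDir, paste0(id, ".geojson")))
    }
    finishStage(outDir, "synth", hash)
  }

  loadCohort <- function() {
    files <- sort(list.files(cohortDir, pattern = "\\.png$",
                             full.names = TRUE))
    if (!length(files))
      stop("missing artifact 'cohort/*.png'; rerun stage 'synth'")
    lapply(files, function(f) {
      id <- tools::file_path_sans_ext(basename(f))
      list(slide = readSlide(f),
           annotations = readAnnotations(
             file.path(cohortDir, paste0(id, ".geojson"))))
    })
  }

  # --- extract -------------------------------------------------------------
  patchesRds <- file.path(outDir, "patches.rds")
  if (!stageDone(outDir, "extract", hash)) {
    say("stage extract: cutting %dx%d tiles", config$tileSize,
        config$tileSize)
    cohort <- loadCohort()
    perSlide <- lapply(cohort, function(entry) {
      sets <- lapply(config$downsampleFactors, function(f) {
        sl <- downsampleSlide(entry$slide, f)
        tissue <- maskBackground(sl, config$whitenessThreshold)
        masks <- rasterizeAnnotations(entry$annotations, dim(sl)[1:2],
                                      tissue = tissue, factor = f)
        extractPatches(sl, masks, config$tileSize, config$stride)
      })
      combinePatchSets(sets)
    })
    patches <- combinePatchSets(perSlide)
    saveRDS(patches, patchesRds)
    finishStage(outDir, "extract", hash)
  }

  # --- train ---------------------------------------------------------------
  modelDir <- file.path(outDir, "model")
  splitsRds <- file.path(outDir, "splits.rds")
  if (!stageDone(outDir, "train", hash)) {
    patches <- readRDS(requireStage(outDir, "extract", patchesRds))
    ids <- unique(patchMeta(patches)$slideId)
    splits <- splitSlides(ids, config$fractions, config$seeds$split)
    saveRDS(splits, splitsRds)
    byGroup <- function(group, tag) {
      sel <- patchMeta(patches)$slideId %in% splits[[group]]
      ps <- patches[which(sel)]
      ps@splitTag <- tag
      ps
    }
    trainSet <- balanceClasses(byGroup("train", "train"),
                               config$seeds$balance)
    say("stage train: %d balanced training patches", length(trainSet))
    clsConfig <- do.call(classifierConfig,
                         c(list(tileSize = config$tileSize),
                           config$classifier))
    model <- buildClassifier(clsConfig, config$seeds$init)
    model <- trainClassifier(model, trainSet, clsConfig,
                             seed = config$seeds$train)
    writeClassifier(model, modelDir)
    finishStage(outDir, "train", hash)
  }

  # --- sweep ---------------------------------------------------------------
  sweepStem <- file.path(outDir, "sweep")
  if (!stageDone(outDir, "sweep", hash)) {
    model <- readClassifier(
      dirname(requireStage(outDir, "train",
                           file.path(modelDir, "model.rds"))))
    patches <- readRDS(requireStage(outDir, "extract", patchesRds))
    splits <- readRDS(requireStage(outDir, "train", splitsRds))
    sel <- patchMeta(patches)$slideId %in% splits$validation
    valSet <- patches[which(sel)]
    if (length(valSet) == 0L)
      stop("validation split holds no patches; enlarge the cohort")
    conf <- predictPatches(model, valSet)
    sweep <- thresholdSweep(conf, patchLabels(valSet),
                            config$sweepGridStep)
    say("stage sweep: best threshold %.2f (f1 %.3f)",
        sweep@bestThreshold, sweep@bestF1)
    writeSweep(sweep, sweepStem)
    finishStage(outDir, "sweep", hash)
  }

  # --- segment -------------------------------------------------------------
  segDir <- file.path(outDir, "segmentation")
  if (!stageDone(outDir, "segment", hash)) {
    model <- readClassifier(modelDir)
    splits <- readRDS(requireStage(outDir, "train", splitsRds))
    sweepJson <- jsonlite::fromJSON(
      requireStage(outDir, "sweep", paste0(sweepStem, ".json")))
    threshold <- if (is.null(config$threshold)) sweepJson$bestThreshold
                 else config$threshold
    cohort <- loadCohort()
    dir.create(segDir, showWarnings = FALSE)
    for (entry in cohort) {
      id <- slideId(entry$slide)
      if (!id %in% splits$test) next
      say("stage segment: %s at step %d, threshold %.2f", id,
          config$segmentStep, threshold)
      seg <- segmentSlide(entry$slide, model, config$segmentStep,
                          threshold)
      writeConfidenceMap(seg$map,
                         file.path(segDir, paste0(id, "_confidence.tif")))
      writeMask(tumorPixels(seg$mask),
                file.path(segDir, paste0(id, "_mask.png")))
      png::writePNG(renderConfidence(seg$map, "jet") / 255,
                    file.path(segDir, paste0(id, "_heatmap.png")))
      png::writePNG(overlayMask(entry$slide, seg$mask) / 255,
                    file.path(segDir, paste0(id, "_overlay.png")))
    }
    finishStage(outDir, "segment", hash)
  }

  # --- evaluate ------------------------------------------------------------
  metricsDir <- file.path(outDir, "metrics")
  model <- readClassifier(
    dirname(requireStage(outDir, "train", file.path(modelDir, "model.rds"))))
  patches <- readRDS(requireStage(outDir, "extract", patchesRds))
  splits <- readRDS(requireStage(outDir, "train", splitsRds))
  sweepJson <- jsonlite::fromJSON(
    requireStage(outDir, "sweep", paste0(sweepStem, ".json")))
  threshold <- if (is.null(config$threshold)) sweepJson$bestThreshold
               else config$threshold
  dir.create(metricsDir, showWarnings = FALSE)
  testSet <- patches[which(patchMeta(patches)$slideId %in% splits$test)]
  kernel <- kernelMetrics(predictPatches(model, testSet),
                          patchLabels(testSet), threshold)
  writeMetrics(kernel, file.path(metricsDir, "kernel"))
  cohort <- loadCohort()
  pixelReports <- list()
  for (entry in cohort) {
    id <- slideId(entry$slide)
    if (!id %in% splits$test) next
    mask <- readMask(requireStage(outDir, "segment",
                                  file.path(segDir,
                                            paste0(id, "_mask.png"))))
    gt <- rasterizeAnnotations(entry$annotations,
                               dim(entry$slide)[1:2])
    pixelReports[[id]] <- pixelMetrics(mask, gt)
    writeMetrics(pixelReports[[id]],
                 file.path(metricsDir, paste0("pixel_", id)))
  }
  macro <- macroAverage(pixelReports)
  utils::write.csv(macro, file.path(metricsDir, "pixel_macro.csv"),
                   row.names = FALSE)
  say("pipeline complete: kernel f1 %.3f, pixel f1 %.3f (macro mean)",
      kernel@f1, macro$mean[macro$metric == "f1"])
  finishStage(outDir, "evaluate", hash)
  invisible(list(model = model, threshold = threshold, kernel = kernel,
                 pixel = pixelReports, pixelMacro = macro))
}
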