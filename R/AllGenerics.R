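#' @include AllClasses.R
NULL

#' Predict tumor confidences for a batch of tiles
#'
#' @param object a classifier (`TumorClassifier` or `FunctionClassifier`).
#' @param tiles an `s x s x 3` tile, an `s x s x 3 x N` batch, or a
#'   [PatchSet-class].
#' @param batchSize mini-batch size used internally for batched evaluation.
#' @return numeric vector of confidences in `[0, 1]`, one per tile, in input
#'   order (0 = healthy, 1 = tumor).
#' @export
setGeneric("predictPatches", function(object, tiles, batchSize = 64L)
  standardGeneric("predictPatches"))

#' @rdname accessors
#' @export
setGeneric("slidePixels", function(object) standardGeneric("slidePixels"))
#' @rdname accessors
#' @export
setGeneric("slideId", function(object) standardGeneric("slideId"))
#' @rdname accessors
#' @export
setGeneric("downsampleFactor", function(object)
  standardGeneric("downsampleFactor"))
#' @rdname accessors
#' @export
setGeneric("regionLabels", function(object) standardGeneric("regionLabels"))
#' @rdname accessors
#' @export
setGeneric("regionPolygons", function(object)
  standardGeneric("regionPolygons"))
#' @rdname accessors
#' @export
setGeneric("tumorMask", function(object) standardGeneric("tumorMask"))
#' @rdname accessors
#' @export
setGeneric("normalMask", function(object) standardGeneric("normalMask"))
#' @rdname accessors
#' @export
setGeneric("annotatedMask", function(object) standardGeneric("annotatedMask"))
#' @rdname accessors
#' @export
setGeneric("tissueMask", function(object) standardGeneric("tissueMask"))
#' @rdname accessors
#' @export
setGeneric("patchTiles", function(object) standardGeneric("patchTiles"))
#' @rdname accessors
#' @export
setGeneric("patchMeta", function(object) standardGeneric("patchMeta"))
#' @rdname accessors
#' @export
setGeneric("patchLabels", function(object) standardGeneric("patchLabels"))
#' @rdname accessors
#' @export
setGeneric("confidence", function(object) standardGeneric("confidence"))
#' @rdname accessors
#' @export
setGeneric("coverage", function(object) standardGeneric("coverage"))
#' @rdname accessors
#' @export
setGeneric("tumorPixels", function(object) standardGeneric("tumorPixels"))
#' @rdname accessors
#' @export
setGeneric("trainingHistory", function(object)
  standardGeneric("trainingHistory"))
#' @rdname accessors
#' @export
setGeneric("bestEpoch", function(object) standardGeneric("bestEpoch"))
#' @rdname accessors
#' @export
setGeneric("isTrained", function(object) standardGeneric("isTrained"))
#' @rdname accessors
#' @export
setGeneric("bestThreshold", function(object) standardGeneric("bestThreshold"))
#' @rdname accessors
#' @export
setGeneric("metricsList", function(object) standardGeneric("metricsList"))

#' Accessor functions for tileseg classes
#'
#' Read-only access to the slots of the package's S4 containers.
#'
#' @param object an instance of a tileseg S4 class.
#' @name accessors
#' @return the corresponding slot value.
NULL

#' @rdname accessors
#' @export
setMethod("slidePixels", "SlideImage", function(object) object@pixels)
#' @rdname accessors
#' @export
setMethod("slideId", "SlideImage", function(object) object@slideId)
#' @rdname accessors
#' @export
setMethod("downsampleFactor", "SlideImage", function(object)
  object@downsampleFactor)
#' @rdname accessors
#' @export
setMethod("regionLabels", "AnnotationSet", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("regionPolygons", "AnnotationSet", function(object) object@polygons)
#' @rdname accessors
#' @export
setMethod("tumorMask", "LabelMasks", function(object) object@tumorMask)
#' @rdname accessors
#' @export
setMethod("normalMask", "LabelMasks", function(object) object@normalMask)
#' @rdname accessors
#' @export
setMethod("annotatedMask", "LabelMasks", function(object)
  object@annotatedMask)
#' @rdname accessors
#' @export
setMethod("tissueMask", "LabelMasks", function(object) object@tissueMask)
#' @rdname accessors
#' @export
setMethod("patchTiles", "PatchSet", function(object) object@tiles)
#' @rdname accessors
#' @export
setMethod("patchMeta", "PatchSet", function(object) object@meta)
#' @rdname accessors
#' @export
setMethod("patchLabels", "PatchSet", function(object) object@meta$label)
#' @rdname accessors
#' @export
setMethod("confidence", "ConfidenceMap", function(object) object@confidence)
#' @rdname accessors
#' @export
setMethod("coverage", "ConfidenceMap", function(object) object@coverage)
#' @rdname accessors
#' @export
setMethod("tumorPixels", "SegmentationMask", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("trainingHistory", "TumorClassifier", function(object)
  object@history)
#' @rdname accessors
#' @export
setMethod("bestEpoch", "TumorClassifier", function(object) object@bestEpoch)
#' @rdname accessors
#' @export
setMethod("isTrained", "TumorClassifier", function(object) object@trained)
#' @rdname accessors
#' @export
setMethod("isTrained", "FunctionClassifier", function(object) TRUE)
#' @rdname accessors
#' @export
setMethod("bestThreshold", "SweepResult", function(object)
  object@bestThreshold)

#' @rdname accessors
#' @export
setMethod("metricsList", "MetricsReport", function(object)
  list(accuracy = object@accuracy, precision = object@precision,
       recall = object@recall, f1 = object@f1, auroc = object@auroc,
       mse = object@mse, n = object@n))

#' Dimensions of a SlideImage
#' @param x a [SlideImage-class].
#' @return integer `c(height, width, 3)`.
#' @export
setMethod("dim", "SlideImage", function(x) dim(x@pixels))

#' Number of regions in an AnnotationSet
#' @param x an [AnnotationSet-class].
#' @export
setMethod("length", "AnnotationSet", function(x) length(x@labels))

#' Number of patches in a PatchSet
#' @param x a [PatchSet-class].
#' @export
setMethod("length", "PatchSet", function(x) nrow(x@meta))

#' Subset a PatchSet by patch index
#' @param x a [PatchSet-class].
#' @param i integer or logical index over patches.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "PatchSet", function(x, i, j, ..., drop = FALSE) {
  idx <- seq_len(length(x))[i]
  new("PatchSet",
      tiles = x@tiles[, , , idx, drop = FALSE],
      meta = x@meta[idx, , drop = FALSE],
      tileSize = x@tileSize,
      splitTag = x@splitTag)
})

setMethod("show", "SlideImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("SlideImage '%s': %d x %d RGB, downsample factor %d\n",
              object@slideId, d[1], d[2], object@downsampleFactor))
  if (!is.na(object@pixelSize))
    cat(sprintf("  pixel size: %.4f um\n", object@pixelSize))
})

setMethod("show", "AnnotationSet", function(object) {
  tab <- table(factor(object@labels, levels = TISSUE_LABELS))
  cat(sprintf("AnnotationSet: %d region(s) (%d tumor, %d normal)\n",
              length(object@labels), tab[["tumor"]], tab[["normal"]]))
})

setMethod("show", "LabelMasks", function(object) {
  d <- dim(object@tumorMask)
  cat(sprintf(
    "LabelMasks %d x %d: %d tumor px, %d normal px, %d tissue px\n",
    d[1], d[2], sum(object@tumorMask), sum(object@normalMask),
    sum(object@tissueMask)))
})

setMethod("show", "PatchSet", function(object) {
  lab <- object@meta$label
  cat(sprintf(
    "PatchSet [%s]: %d tiles of %d x %d (%d tumor / %d normal)\n",
    object@splitTag, length(object), object@tileSize, object@tileSize,
    sum(lab == 1), sum(lab == 0)))
})

setMethod("show", "TumorClassifier", function(object) {
  np <- length(unlist(object@params))
  cat(sprintf("TumorClassifier: %s, %d parameters\n",
              if (object@trained) "trained" else "untrained", np))
  if (object@trained)
    cat(sprintf("  %d epoch(s), best validation loss %.4g at epoch %d\n",
                nrow(object@history),
                object@history$valLoss[object@bestEpoch], object@bestEpoch))
})

setMethod("show", "FunctionClassifier", function(object) {
  cat("FunctionClassifier (deterministic tile-scoring function)\n")
})

setMethod("show", "ConfidenceMap", function(object) {
  d <- dim(object@confidence)
  cat(sprintf(
    "ConfidenceMap %d x %d: window %d, step %d, coverage %d..%d\n",
    d[1], d[2], object@window, object@step,
    min(object@coverage), max(object@coverage)))
})

setMethod("show", "SegmentationMask", function(object) {
  cat(sprintf(
    "SegmentationMask %d x %d: %d tumor px (threshold %.2f, step %d)\n",
    nrow(object@mask), ncol(object@mask), sum(object@mask),
    object@threshold, object@step))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(paste0(
    "MetricsReport (n = %d)\n",
    "  accuracy %.4f  precision %.4f  recall %.4f\n",
    "  f1 %.4f  auroc %s  mse %.4f\n"),
    object@n, object@accuracy, object@precision, object@recall,
    object@f1, ifelse(is.na(object@auroc), "NA",
                      sprintf("%.4f", object@auroc)), object@mse))
  m <- object@confusion
  cat(sprintf("  confusion (truth x prediction): TP %d FN %d / FP %d TN %d\n",
              m[1, 1], m[1, 2], m[2, 1], m[2, 2]))
})

setMethod("show", "SweepResult", function(object) {
  cat(sprintf(
    "SweepResult: %d thresholds, best f1 %.4f at threshold %.2f\n",
    length(object@thresholds), object@bestF1, object@bestThreshold))
})

setMethod("show", "SyntheticSlideSpec", function(object) {
  cat(sprintf(
    "SyntheticSlideSpec: %d x %d canvas, %d tumor + %d normal region(s)\n",
    object@height, object@width, object@nTumorRegions,
    object@nNormalRegions))
})
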