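#' @import methods
NULL

TISSUE_LABELS <- c("normal", "tumor")

#' SlideImage: an 8-bit RGB slide raster with resolution metadata
#'
#' Container for a (possibly downsampled) whole-slide RGB image. Pixels are
#' stored as an `H x W x 3` numeric array of integer intensities in
#' `[0, 255]`, row/column indexed (row 1 = top of the slide).
#'
#' @slot pixels numeric `H x W x 3` array, intensities in `[0, 255]`.
#' @slot downsampleFactor integer >= 1; 1 means native resolution.
#' @slot pixelSize micrometers per pixel at this resolution (`NA` if unknown).
#' @slot slideId character identifier.
#'
#' @exportClass SlideImage
setClass("SlideImage",
  representation(
    pixels = "array",
    downsampleFactor = "integer",
    pixelSize = "numeric",
    slideId = "character"
  ),
  prototype(
    downsampleFactor = 1L,
    pixelSize = NA_real_,
    slideId = "slide"
  )
)

setValidity("SlideImage", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "pixels must be an H x W x 3 array")
  else {
    if (d[1] < 1L || d[2] < 1L)
      msg <- c(msg, "height and width must be >= 1")
    rng <- range(object@pixels)
    if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
      msg <- c(msg, "intensities must lie in [0, 255]")
  }
  if (length(object@downsampleFactor) != 1L || object@downsampleFactor < 1L)
    msg <- c(msg, "downsampleFactor must be a single integer >= 1")
  if (length(msg)) msg else TRUE
})

#' AnnotationSet: labeled polygon regions in slide pixel coordinates
#'
#' Area-based annotations: each region is a polygon (optionally with interior
#' rings acting as holes) carrying a label in `{tumor, normal}`. Coordinates
#' are 0-based `(x, y)` pairs in native slide pixels, as GeoJSON dictates;
#' pixel `(row r, col c)` has its center at `(x = c, y = r)`.
#'
#' @slot polygons list; element i is a list of rings, each an `n x 2` numeric
#'   matrix of `(x, y)` vertices. Ring 1 is the outer boundary, further rings
#'   are holes.
#' @slot labels character vector, one of `"tumor"`/`"normal"` per region.
#'
#' @exportClass AnnotationSet
setClass("AnnotationSet",
  representation(polygons = "list", labels = "character"),
  prototype(polygons = list(), labels = character())
)

setValidity("AnnotationSet", function(object) {
  msg <- character()
  if (length(object@polygons) != length(object@labels))
    msg <- c(msg, "polygons and labels must have equal length")
  if (!all(object@labels %in% TISSUE_LABELS))
    msg <- c(msg, sprintf("labels must be one of: %s",
                          paste(TISSUE_LABELS, collapse = ", ")))
  for (i in seq_along(object@polygons)) {
    rings <- object@polygons[[i]]
    if (!is.list(rings) || length(rings) < 1L) {
      msg <- c(msg, sprintf("region %d: must be a non-empty list of rings", i))
      next
    }
    for (ring in rings) {
      if (!is.matrix(ring) || ncol(ring) != 2L || nrow(ring) < 3L)
        msg <- c(msg, sprintf(
          "region %d: every ring needs >= 3 (x, y) vertices", i))
    }
  }
  if (length(msg)) msg else TRUE
})

#' LabelMasks: rasterized ground-truth and tissue masks
#'
#' Per-pixel boolean masks at a single resolution. `tumorMask` and
#' `normalMask` are disjoint; `annotatedMask` is their union (area-based
#' annotation leaves the rest of the tissue unlabeled). `tissueMask` marks
#' non-background pixels.
#'
#' @slot tumorMask,normalMask,annotatedMask,tissueMask logical `H x W`
#'   matrices.
#'
#' @exportClass LabelMasks
setClass("LabelMasks",
  representation(
    tumorMask = "matrix",
    normalMask = "matrix",
    annotatedMask = "matrix",
    tissueMask = "matrix"
  )
)

setValidity("LabelMasks", function(object) {
  msg <- character()
  dims <- lapply(list(object@tumorMask, object@normalMask,
                      object@annotatedMask, object@tissueMask), dim)
  if (length(unique(dims)) != 1L)
    msg <- c(msg, "all masks must share one H x W shape")
  if (any(object@tumorMask & object@normalMask))
    msg <- c(msg, "tumorMask and normalMask overlap")
  if (!identical(object@annotatedMask, object@tumorMask | object@normalMask))
    msg <- c(msg, "annotatedMask must equal tumorMask | normalMask")
  if (length(msg)) msg else TRUE
})

#' PatchSet: labeled fixed-size tiles with provenance
#'
#' A collection of square RGB tiles cut from annotated slide regions,
#' together with a manifest recording where each tile came from. Labels are
#' 1 = tumor, 0 = normal.
#'
#' @slot tiles numeric `s x s x 3 x N` array of 8-bit intensities.
#' @slot meta data.frame with columns `slideId`, `row`, `col` (0-based
#'   top-left corner in slide coordinates), `label` (0/1) and `factor`
#'   (downsample factor of the source slide).
#' @slot tileSize integer tile side length.
#' @slot splitTag one of `"train"`, `"validation"`, `"test"`, `"unsplit"`.
#'
#' @exportClass PatchSet
setClass("PatchSet",
  representation(
    tiles = "array",
    meta = "data.frame",
    tileSize = "integer",
    splitTag = "character"
  ),
  prototype(splitTag = "unsplit")
)

setValidity("PatchSet", function(object) {
  msg <- character()
  d <- dim(object@tiles)
  if (length(d) != 4L || d[3] != 3L)
    msg <- c(msg, "tiles must be an s x s x 3 x N array")
  else {
    if (d[1] != object@tileSize || d[2] != object@tileSize)
      msg <- c(msg, "tile shape must be tileSize x tileSize x 3")
    if (d[4] != nrow(object@meta))
      msg <- c(msg, "meta must have one row per tile")
  }
  need <- c("slideId", "row", "col", "label", "factor")
  if (!all(need %in% names(object@meta)))
    msg <- c(msg, sprintf("meta must have columns: %s",
                          paste(need, collapse = ", ")))
  else if (nrow(object@meta) && !all(object@meta$label %in% c(0, 1)))
    msg <- c(msg, "labels must be 0 (normal) or 1 (tumor)")
  if (length(msg)) msg else TRUE
})

#' TumorClassifier: the compact convolutional patch classifier
#'
#' Four valid convolutions (filters 8, 16, 16, 32; kernels 3x3, 3x3, 5x5,
#' 3x3), each followed by batch normalization, SELU activation and 2x2 max
#' pooling, then global average pooling and a 2-unit softmax head. The
#' softmax tumor probability is the confidence in `[0, 1]` (0 = healthy,
#' 1 = tumor).
#'
#' @slot config list of hyperparameters (see [classifierConfig()]).
#' @slot params list of learned weights.
#' @slot state list of batch-norm running statistics (frozen at inference).
#' @slot trained logical; `TRUE` after [trainClassifier()].
#' @slot history data.frame of per-epoch train/validation loss.
#' @slot bestEpoch integer index of the restored (minimum validation loss)
#'   epoch; `NA` before training.
#'
#' @exportClass TumorClassifier
setClass("TumorClassifier",
  representation(
    config = "list",
    params = "list",
    state = "list",
    trained = "logical",
    history = "data.frame",
    bestEpoch = "integer"
  ),
  prototype(trained = FALSE, bestEpoch = NA_integer_,
            history = data.frame())
)

#' FunctionClassifier: a deterministic tile-scoring function as a classifier
#'
#' Wraps an arbitrary R function `tile -> confidence in [0, 1]` in the
#' classifier interface. Useful as a mock model for exercising the
#' segmentation machinery independently of training.
#'
#' @slot fn function taking one `s x s x 3` tile array and returning a single
#'   confidence in `[0, 1]`.
#'
#' @exportClass FunctionClassifier
setClass("FunctionClassifier", representation(fn = "function"))

#' ConfidenceMap: per-pixel mean tumor confidence with coverage counts
#'
#' @slot confidence numeric `H x W` matrix; mean confidence over all sliding
#'   windows covering each pixel, `-1` sentinel where coverage is 0.
#' @slot coverage integer `H x W` matrix of covering-window counts.
#' @slot window,step integer sliding-window side and stride.
#'
#' @exportClass ConfidenceMap
setClass("ConfidenceMap",
  representation(
    confidence = "matrix",
    coverage = "matrix",
    window = "integer",
    step = "integer"
  )
)

setValidity("ConfidenceMap", function(object) {
  msg <- character()
  if (!identical(dim(object@confidence), dim(object@coverage)))
    msg <- c(msg, "confidence and coverage must share one shape")
  cov <- object@coverage > 0
  vals <- object@confidence[cov]
  if (length(vals) && (min(vals) < 0 || max(vals) > 1))
    msg <- c(msg, "covered confidences must lie in [0, 1]")
  if (any(object@confidence[!cov] != -1))
    msg <- c(msg, "uncovered pixels must hold the -1 sentinel")
  if (length(msg)) msg else TRUE
})

#' SegmentationMask: binarized tumor mask with its provenance
#'
#' @slot mask logical `H x W`; `TRUE` = tumor (confidence >= threshold on
#'   covered pixels).
#' @slot threshold numeric binarization threshold used.
#' @slot step integer sliding-window stride used.
#'
#' @exportClass SegmentationMask
setClass("SegmentationMask",
  representation(mask = "matrix", threshold = "numeric", step = "integer")
)

#' MetricsReport: classification metrics plus the confusion matrix
#'
#' Scores are fractions in `[0, 1]`. The confusion matrix has truth in rows
#' (tumor, normal) and prediction in columns; `rates` is the row-normalized
#' version (each truth row sums to 1).
#'
#' @slot accuracy,precision,recall,f1,auroc,mse numeric scalars (possibly
#'   `NA` where undefined, e.g. AUROC on single-class truth).
#' @slot confusion 2x2 numeric count matrix.
#' @slot rates 2x2 numeric row-normalized matrix.
#' @slot n integer number of evaluated items.
#'
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(
    accuracy = "numeric", precision = "numeric", recall = "numeric",
    f1 = "numeric", auroc = "numeric", mse = "numeric",
    confusion = "matrix", rates = "matrix", n = "integer"
  )
)

#' SweepResult: F1 threshold sweep over a grid on [0, 1]
#'
#' @slot thresholds numeric grid.
#' @slot f1 numeric F1 at each grid point.
#' @slot bestThreshold lowest grid point attaining the maximum F1.
#' @slot bestF1 the maximum F1.
#'
#' @exportClass SweepResult
setClass("SweepResult",
  representation(
    thresholds = "numeric", f1 = "numeric",
    bestThreshold = "numeric", bestF1 = "numeric"
  )
)

setValidity("SweepResult", function(object) {
  msg <- character()
  if (length(object@thresholds) != length(object@f1))
    msg <- c(msg, "thresholds and f1 must have equal length")
  if (abs(object@bestF1 - max(object@f1)) > 1e-12)
    msg <- c(msg, "bestF1 must be the maximum of f1")
  if (length(msg)) msg else TRUE
})

#' SyntheticSlideSpec: parameters of the synthetic histology generator
#'
#' Describes a bright-field-like slide: a white background carrying
#' non-overlapping rectangular tissue regions of two classes. Each region is
#' a cytoplasm-colored field scattered with dark elliptic nuclei; tumor
#' regions emulate hypercellularity through a higher nucleus density and
#' larger nuclei. Additive Gaussian color jitter gives within-class
#' variability.
#'
#' @slot height,width canvas size in pixels.
#' @slot nTumorRegions,nNormalRegions region counts per class.
#' @slot regionSizeRange min/max region side length in pixels.
#' @slot tumorDensity,normalDensity expected nuclei per 1000 px^2.
#' @slot tumorRadiusRange,normalRadiusRange nucleus radius range in pixels.
#' @slot nucleusColor,cytoplasmColor,background RGB triples in `[0, 255]`.
#' @slot jitterSd standard deviation of the additive color jitter.
#' @slot minSeparation minimum gap between regions in pixels (kept larger
#'   than a tile so no sliding window straddles two regions).
#' @slot maxPlacementTries rejection-sampling budget before failing.
#'
#' @exportClass SyntheticSlideSpec
setClass("SyntheticSlideSpec",
  representation(
    height = "integer", width = "integer",
    nTumorRegions = "integer", nNormalRegions = "integer",
    regionSizeRange = "integer",
    tumorDensity = "numeric", normalDensity = "numeric",
    tumorRadiusRange = "numeric", normalRadiusRange = "numeric",
    nucleusColor = "numeric", cytoplasmColor = "numeric",
    background = "numeric", jitterSd = "numeric",
    minSeparation = "integer", maxPlacementTries = "integer"
  )
)

setValidity("SyntheticSlideSpec", function(object) {
  msg <- character()
  if (object@height < 1L || object@width < 1L)
    msg <- c(msg, "canvas must be at least 1 x 1")
  if (object@nTumorRegions < 0L || object@nNormalRegions < 0L)
    msg <- c(msg, "region counts must be >= 0")
  if (length(object@regionSizeRange) != 2L ||
      object@regionSizeRange[1] > object@regionSizeRange[2] ||
      object@regionSizeRange[1] < 1L)
    msg <- c(msg, "regionSizeRange must be increasing and positive")
  for (nm in c("nucleusColor", "cytoplasmColor", "background")) {
    v <- slot(object, nm)
    if (length(v) != 3L || any(v < 0) || any(v > 255))
      msg <- c(msg, sprintf("%s must be an RGB triple in [0, 255]", nm))
  }
  if (object@tumorDensity < 0 || object@normalDensity < 0)
    msg <- c(msg, "densities must be >= 0")
  if (length(msg)) msg else TRUE
})
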