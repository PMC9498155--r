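#' @include AllClasses.R AllGenerics.R classifier.R
NULL

axisAnchors <- function(extent, window, step) {
  a <- seq.int(0L, extent - window, by = step)
  if (a[length(a)] != extent - window) a <- c(a, extent - window)
  a
}

#' Sliding-window anchor positions
#'
#' Anchors sit at multiples of `step`; when the last multiple does not bring
#' the window flush with the image border, one extra border-flush anchor is
#' appended per axis so that every pixel is covered by at least one window.
#'
#' @param height,width image extent in pixels.
#' @param window window side (default 128).
#' @param step stride between anchors, `1 <= step <= window`.
#' @return integer matrix with columns `row`, `col` of 0-based top-left
#'   anchors, ordered row-major.
#' @export
slidingPositions <- function(height, width, window = 128L, step) {
  height <- asIntegerStrict(height, "height")
  width <- asIntegerStrict(width, "width")
  window <- asIntegerStrict(window, "window")
  step <- asIntegerStrict(step, "step")
  if (window > height || window > width)
    stop("window larger than the image")
  if (step < 1L || step > window)
    stop("step must satisfy 1 <= step <= window")
  rows <- axisAnchors(height, window, step)
  cols <- axisAnchors(width, window, step)
  cbind(row = rep(rows, each = length(cols)),
        col = rep(cols, times = length(rows)))
}

#' Overlapping predictions per interior pixel
#'
#' Counts, by explicit enumeration of stride-grid anchors, how many window
#' placements contain a fixed pixel far from every border. For window `w`
#' and step `s` dividing it the count is `(w/s)^2` per axis pair: 1 at step
#' 128, 4 at 64, 16 at 32, 64 at 16 and 256 at 8 for the default window.
#'
#' @param window window side (default 128).
#' @param step stride; must divide `window`.
#' @return integer count of windows covering an interior pixel.
#' @export
predictionsPerPixel <- function(window = 128L, step) {
  window <- asIntegerStrict(window, "window")
  step <- asIntegerStrict(step, "step")
  if (step < 1L || window %% step != 0L)
    stop("step must divide window")
  # enumerate anchors around an interior pixel rather than using the closed
  # form: anchor grid a*step with a*step <= p < a*step + window
  p <- 4L * window                       # any pixel far from the borders
  anchors <- seq.int(0L, 8L * window, by = step)
  perAxis <- sum(anchors <= p & p < anchors + window)
  perAxis * perAxis
}

#' Segment a whole slide by sliding-window confidence aggregation
#'
#' Evaluates the classifier on every window placement from
#' [slidingPositions()] (batched), accumulates each prediction over the
#' window's footprint and divides by the per-pixel coverage count, so each
#' pixel's confidence is the arithmetic mean of all windows containing it.
#' The mask binarizes the mean map with `confidence >= threshold` (ties go
#' to tumor — the conservative choice for a diagnostic aid).
#'
#' @param slide a [SlideImage-class] at a resolution comparable to the
#'   training data.
#' @param model a trained [TumorClassifier-class] or a
#'   [FunctionClassifier-class].
#' @param step sliding-window stride in pixels.
#' @param threshold binarization threshold in `[0, 1]` (see
#'   [thresholdSweep()]).
#' @param window window side (default 128).
#' @param batchSize tiles per prediction batch.
#' @return list with elements `map` ([ConfidenceMap-class]) and `mask`
#'   ([SegmentationMask-class]).
#' @export
segmentSlide <- function(slide, model, step, threshold = 0.5,
                         window = 128L, batchSize = 64L) {
  if (!is(slide, "SlideImage")) stop("slide must be a SlideImage")
  if (!isTrained(model))
    stop("model is untrained; run trainClassifier() first")
  d <- dim(slide@pixels)
  step <- asIntegerStrict(step, "step")
  window <- asIntegerStrict(window, "window")
  pos <- slidingPositions(d[1], d[2], window, step)
  sumMap <- matrix(0, d[1], d[2])
  cntMap <- matrix(0L, d[1], d[2])
  n <- nrow(pos)
  for (start in seq(1L, n, by = batchSize)) {
    take <- start:min(start + batchSize - 1L, n)
    tiles <- array(0, c(window, window, 3L, length(take)))
    for (k in seq_along(take)) {
      r0 <- pos[take[k], 1]; c0 <- pos[take[k], 2]
      tiles[, , , k] <- slide@pixels[r0 + seq_len(window),
                                     c0 + seq_len(window), , drop = FALSE]
    }
    conf <- predictPatches(model, tiles, batchSize = batchSize)
    for (k in seq_along(take)) {
      r <- pos[take[k], 1] + seq_len(window)
      c <- pos[take[k], 2] + seq_len(window)
      sumMap[r, c] <- sumMap[r, c] + conf[k]
      cntMap[r, c] <- cntMap[r, c] + 1L
    }
  }
  mean <- ifelse(cntMap > 0L, sumMap / pmax(cntMap, 1L), -1)
  map <- new("ConfidenceMap", confidence = mean, coverage = cntMap,
             window = window, step = step)
  mask <- new("SegmentationMask",
              mask = cntMap > 0L & mean >= threshold,
              threshold = threshold, step = step)
  list(map = map, mask = mask)
}

#' Binarize a confidence map at a threshold
#'
#' @param map a [ConfidenceMap-class].
#' @param threshold numeric in `[0, 1]`; covered pixels with mean confidence
#'   `>= threshold` become tumor.
#' @return a [SegmentationMask-class].
#' @export
binarizeMap <- function(map, threshold) {
  if (!is(map, "ConfidenceMap")) stop("map must be a ConfidenceMap")
  new("SegmentationMask",
      mask = map@coverage > 0L & map@confidence >= threshold,
      threshold = threshold, step = map@step)
}

# Matplotlib-style jet colormap on [0, 1]: dark blue through cyan, yellow
# and orange to dark red.
jetColor <- function(v) {
  interp <- function(x) pmin(pmax(x, 0), 1)
  r <- interp(1.5 - abs(4 * v - 3))
  g <- interp(1.5 - abs(4 * v - 2))
  b <- interp(1.5 - abs(4 * v - 1))
  list(r = r, g = g, b = b)
}

#' Render a confidence map as an RGB heatmap
#'
#' `grayscale` maps confidence 0 to white and 1 to black, linearly in
#' between; `jet` runs from blue (0) to red (1). Pixels never covered by a
#' window are painted a magenta sentinel so they cannot be mistaken for a
#' confidence value.
#'
#' @param map a [ConfidenceMap-class].
#' @param palette `"grayscale"` or `"jet"`.
#' @return `H x W x 3` numeric array of 8-bit intensities.
#' @export
renderConfidence <- function(map, palette = c("grayscale", "jet")) {
  palette <- match.arg(palette)
  v <- map@confidence
  covered <- map@coverage > 0L
  d <- dim(v)
  out <- array(0, c(d, 3L))
  if (palette == "grayscale") {
    g <- round(255 * (1 - v))
    out[, , 1] <- g; out[, , 2] <- g; out[, , 3] <- g
  } else {
    jc <- jetColor(v)
    out[, , 1] <- round(255 * jc$r)
    out[, , 2] <- round(255 * jc$g)
    out[, , 3] <- round(255 * jc$b)
  }
  sentinel <- c(255, 0, 255)
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[!covered] <- sentinel[ch]
    out[, , ch] <- plane
  }
  out
}

#' Delineate a tumor mask on the original slide
#'
#' Alpha-blends the mask support with a highlight color (yellow by default,
#' the usual annotation color for tumor); pixels outside the mask are
#' returned untouched.
#'
#' @param slide a [SlideImage-class].
#' @param mask a [SegmentationMask-class] or logical matrix of the same
#'   shape.
#' @param color RGB triple of the highlight.
#' @param alpha blend weight of the highlight in `[0, 1]`.
#' @return `H x W x 3` numeric array of 8-bit intensities.
#' @export
overlayMask <- function(slide, mask, color = c(255, 255, 0), alpha = 0.45) {
  if (!is(slide, "SlideImage")) stop("slide must be a SlideImage")
  m <- if (is(mask, "SegmentationMask")) mask@mask else mask
  if (!identical(dim(m), dim(slide@pixels)[1:2]))
    stop("mask shape must equal slide shape")
  out <- slide@pixels
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[m] <- round((1 - alpha) * plane[m] + alpha * color[ch])
    out[, , ch] <- plane
  }
  out
}

#' Persist / load a confidence map
#'
#' The mean-confidence plane goes to a 32-bit TIFF (values quantized at
#' 2^-32, far below any tolerance used here); coverage counts and the
#' window/step parameters go to an RDS sidecar next to it. Uncovered pixels
#' are stored as 0 in the TIFF and restored to the `-1` sentinel from the
#' coverage plane on read.
#'
#' @param map a [ConfidenceMap-class].
#' @param path TIFF path; the sidecar gets the extension `.meta.rds`.
#' @return `readConfidenceMap` returns the [ConfidenceMap-class].
#' @export
writeConfidenceMap <- function(map, path) {
  if (!is(map, "ConfidenceMap")) stop("map must be a ConfidenceMap")
  tiff::writeTIFF(pmax(map@confidence, 0), path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  saveRDS(list(coverage = map@coverage, window = map@window,
               step = map@step),
          paste0(path, ".meta.rds"))
  invisible(path)
}

#' @rdname writeConfidenceMap
#' @export
readConfidenceMap <- function(path) {
  conf <- tiff::readTIFF(path)
  meta <- readRDS(paste0(path, ".meta.rds"))
  conf[meta$coverage == 0L] <- -1
  new("ConfidenceMap", confidence = conf, coverage = meta$coverage,
      window = meta$window, step = meta$step)
}
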