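#' @include AllClasses.R evaluation.R segmentation.R
NULL

#' F1-driven threshold sweep
#'
#' Evaluates the F1 score of the `c >= t => tumor` rule at every grid point
#' over `[0, 1]` and returns the grid, the F1 trace and the best threshold.
#' Ties are broken toward the lowest threshold, favoring sensitivity (a
#' lower threshold never removes tumor calls).
#'
#' @param confidences numeric vector of patch confidences.
#' @param labels 0/1 vector of the same length, both classes present.
#' @param gridStep grid spacing (default 0.01, i.e. thresholds
#'   0.00, 0.01, ..., 1.00).
#' @return a [SweepResult-class].
#' @export
thresholdSweep <- function(confidences, labels, gridStep = 0.01) {
  if (length(confidences) != length(labels))
    stop("confidences and labels must have equal length")
  if (length(unique(labels)) < 2L)
    stop("threshold sweep requires both classes present")
  if (gridStep <= 0 || gridStep > 1) stop("gridStep must lie in (0, 1]")
  grid <- seq(0, 1, by = gridStep)
  if (grid[length(grid)] < 1) grid <- c(grid, 1)
  nPos <- sum(labels == 1)
  f1 <- vapply(grid, function(t) {
    pred <- confidences >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    denom <- 2 * tp + fp + (nPos - tp)
    if (denom == 0) 0 else 2 * tp / denom
  }, numeric(1))
  bestIdx <- which(f1 == max(f1))[1]         # lowest threshold wins ties
  new("SweepResult", thresholds = grid, f1 = f1,
      bestThreshold = grid[bestIdx], bestF1 = f1[bestIdx])
}

#' Step-size time-accuracy trade-off table
#'
#' Segments every slide at each step size with a fixed threshold, evaluates
#' pixel-level metrics against the ground-truth masks and macro-averages
#' them across slides. Wall-clock seconds are recorded per step for user
#' information only — they depend on the hardware and are never part of any
#' correctness claim.
#'
#' @param slides list of [SlideImage-class] objects.
#' @param groundTruth list of matching [LabelMasks-class] objects.
#' @param model a trained classifier.
#' @param steps integer vector of strides (default `c(128, 64, 32, 16, 8)`).
#' @param threshold binarization threshold (typically the
#'   [thresholdSweep()] winner).
#' @param window window side (default 128).
#' @param batchSize tiles per prediction batch.
#' @return data.frame with one row per step: mean/sd accuracy and F1 across
#'   slides, number of window evaluations per slide (mean) and mean
#'   evaluation seconds.
#' @export
stepsizeTradeoff <- function(slides, groundTruth, model,
                             steps = c(128L, 64L, 32L, 16L, 8L),
                             threshold, window = 128L, batchSize = 64L) {
  if (length(slides) != length(groundTruth))
    stop("slides and groundTruth must have equal length")
  rows <- lapply(steps, function(s) {
    reports <- vector("list", length(slides))
    secs <- numeric(length(slides))
    evals <- numeric(length(slides))
    for (i in seq_along(slides)) {
      t0 <- proc.time()[["elapsed"]]
      seg <- segmentSlide(slides[[i]], model, step = s,
                          threshold = threshold, window = window,
                          batchSize = batchSize)
      secs[i] <- proc.time()[["elapsed"]] - t0
      d <- dim(slides[[i]])
      evals[i] <- nrow(slidingPositions(d[1], d[2], window, s))
      reports[[i]] <- pixelMetrics(seg$mask, groundTruth[[i]])
    }
    ma <- macroAverage(reports)
    get <- function(metric, col) ma[ma$metric == metric, col]
    data.frame(step = s,
               accuracyMean = get("accuracy", "mean"),
               accuracySd = get("accuracy", "sd"),
               f1Mean = get("f1", "mean"),
               f1Sd = get("f1", "sd"),
               evaluationsPerSlide = mean(evals),
               secondsMean = mean(secs))
  })
  do.call(rbind, rows)
}

#' Write a sweep result to CSV and JSON
#'
#' @param sweep a [SweepResult-class].
#' @param stem output path stem (without extension).
#' @export
writeSweep <- function(sweep, stem) {
  utils::write.csv(data.frame(threshold = sweep@thresholds, f1 = sweep@f1),
                   paste0(stem, ".csv"), row.names = FALSE)
  writeLines(jsonlite::toJSON(list(bestThreshold = sweep@bestThreshold,
                                   bestF1 = sweep@bestF1),
                              auto_unbox = TRUE, digits = NA),
             paste0(stem, ".json"))
  invisible(stem)
}
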