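#' @include AllClasses.R
NULL

# Build a MetricsReport from binary predictions/truth (1 = tumor) and
# optionally the raw confidences (for AUROC / MSE against labels).
metricsFromBinary <- function(pred, truth, confidences = NULL) {
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  n <- tp + fp + fn + tn
  accuracy <- (tp + tn) / n
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    warning("precision + recall is zero or undefined; reporting f1 = 0")
    0
  }
  if (is.null(confidences)) {
    auroc <- NA_real_
    mse <- mean((pred - truth)^2)
  } else {
    auroc <- if (length(unique(truth)) < 2L) {
      warning("AUROC undefined for single-class truth; reporting NA")
      NA_real_
    } else {
      rocCurve(confidences, truth)$auroc
    }
    mse <- mean((confidences - truth)^2)
  }
  confusion <- matrix(c(tp, fn, fp, tn), 2, 2, byrow = TRUE,
                      dimnames = list(truth = c("tumor", "normal"),
                                      prediction = c("tumor", "normal")))
  rates <- confusion / pmax(rowSums(confusion), 1)
  new("MetricsReport", accuracy = accuracy,
      precision = ifelse(is.na(precision), 0, precision),
      recall = ifelse(is.na(recall), 0, recall),
      f1 = f1, auroc = auroc, mse = mse,
      confusion = confusion, rates = rates, n = as.integer(n))
}

#' Kernel-level (patch) metrics
#'
#' Binarizes the confidences at `threshold` with the `c >= t => tumor` rule
#' and reports accuracy, precision, recall, F1, AUROC (threshold-free, on
#' the raw confidences), MSE (raw confidences against the 0/1 labels) and
#' the confusion matrix.
#'
#' @param confidences numeric vector in `[0, 1]`.
#' @param labels integer vector of 0 (normal) / 1 (tumor), same length.
#' @param threshold binarization threshold.
#' @return a [MetricsReport-class].
#' @export
kernelMetrics <- function(confidences, labels, threshold = 0.5) {
  if (length(confidences) != length(labels))
    stop("confidences and labels must have equal length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  metricsFromBinary(as.integer(confidences >= threshold), labels,
                    confidences)
}

#' Pixel-level metrics against area-based ground truth
#'
#' Compares the binarized segmentation with the rasterized annotations,
#' restricted to the annotated pixels: area-based annotation only marks
#' regions that are surely tumor or surely normal, so unannotated pixels
#' carry no ground truth and are excluded rather than counted as negatives.
#' The positive class is tumor.
#'
#' @param mask a [SegmentationMask-class] or logical matrix.
#' @param gt a [LabelMasks-class] of the same shape.
#' @return a [MetricsReport-class] (AUROC is `NA`: a binary mask carries no
#'   ranking).
#' @export
pixelMetrics <- function(mask, gt) {
  m <- if (is(mask, "SegmentationMask")) mask@mask else mask
  if (!is(gt, "LabelMasks")) stop("gt must be a LabelMasks")
  if (!identical(dim(m), dim(gt@tumorMask)))
    stop("mask and ground truth shapes differ")
  sel <- gt@annotatedMask
  if (!any(sel)) stop("empty annotated mask: nothing to evaluate")
  metricsFromBinary(as.integer(m[sel]), as.integer(gt@tumorMask[sel]))
}

#' ROC curve and area under it
#'
#' Operating points are generated by the `c >= t` decision rule at every
#' distinct confidence (plus the all-negative end); the area is the
#' trapezoidal integral over (fpr, tpr), which equals the Mann-Whitney
#' concordance probability.
#'
#' @param confidences numeric vector.
#' @param labels 0/1 vector of the same length.
#' @return list with `fpr`, `tpr`, `thresholds` (parallel vectors, fpr
#'   increasing) and `auroc`.
#' @export
rocCurve <- function(confidences, labels) {
  if (length(confidences) != length(labels))
    stop("confidences and labels must have equal length")
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  if (nPos == 0L || nNeg == 0L)
    stop("ROC requires both classes present")
  thr <- c(Inf, sort(unique(confidences), decreasing = TRUE))
  tpr <- fpr <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred <- confidences >= thr[i]
    tpr[i] <- sum(pred & labels == 1) / nPos
    fpr[i] <- sum(pred & labels == 0) / nNeg
  }
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = thr, auroc = auroc)
}

#' Macro-average per-slide metric reports
#'
#' Slide-level metrics are averaged with their standard deviation — the
#' mean +/- sd presentation used for whole-slide benchmarks — alongside the
#' pooled interpretation available by evaluating all pixels together.
#'
#' @param reports list of [MetricsReport-class] objects (one per slide).
#' @return data.frame with one row per metric: `mean`, `sd`, `n`.
#' @export
macroAverage <- function(reports) {
  vals <- vapply(reports, function(r)
    c(accuracy = r@accuracy, precision = r@precision, recall = r@recall,
      f1 = r@f1, auroc = r@auroc, mse = r@mse), numeric(6))
  data.frame(metric = rownames(vals),
             mean = rowMeans(vals, na.rm = TRUE),
             sd = apply(vals, 1, stats::sd, na.rm = TRUE),
             n = length(reports),
             row.names = NULL)
}

#' Write a MetricsReport to JSON and CSV
#'
#' `<stem>.json` holds the scalar metrics, `<stem>_confusion.csv` the count
#' and rate matrices.
#'
#' @param report a [MetricsReport-class].
#' @param stem output path stem (without extension).
#' @export
writeMetrics <- function(report, stem) {
  writeLines(jsonlite::toJSON(metricsList(report), auto_unbox = TRUE,
                              digits = NA, na = "null"),
             paste0(stem, ".json"))
  cm <- cbind(truth = rownames(report@confusion),
              as.data.frame(unclass(report@confusion)),
              stats::setNames(as.data.frame(unclass(report@rates)),
                              c("rate.tumor", "rate.normal")))
  utils::write.csv(cm, paste0(stem, "_confusion.csv"), row.names = FALSE)
  invisible(stem)
}
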