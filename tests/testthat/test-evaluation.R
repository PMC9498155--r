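test_that("kernel metrics match hand-computed contingency values", {
  perfect <- kernelMetrics(c(1, 1, 0, 0), c(1, 1, 0, 0), 0.5)
  for (m in c("accuracy", "precision", "recall", "f1", "auroc"))
    expect_equal(slot(perfect, m), 1)
  expect_equal(perfect@mse, 0)

  toy <- kernelMetrics(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0), 0.5)
  expect_equal(unname(toy@confusion["tumor", "tumor"]), 1)    # TP
  expect_equal(unname(toy@confusion["normal", "tumor"]), 1)   # FP
  expect_equal(unname(toy@confusion["tumor", "normal"]), 1)   # FN
  expect_equal(unname(toy@confusion["normal", "normal"]), 1)  # TN
  expect_equal(toy@precision, 0.5)
  expect_equal(toy@recall, 0.5)
  expect_equal(toy@f1, 0.5)
  expect_equal(sum(toy@confusion), toy@n)
  expect_equal(unname(rowSums(toy@rates)), c(1, 1))
  expect_equal(toy@mse, mean((c(0.9, 0.8, 0.3, 0.2) - c(1, 0, 1, 0))^2))

  expect_warning(
    inverted <- kernelMetrics(c(0, 0, 1, 1), c(1, 1, 0, 0), 0.5),
    "reporting f1 = 0")
  expect_equal(inverted@accuracy, 0)
  expect_equal(inverted@auroc, 0)

  expect_warning(single <- kernelMetrics(c(0.9, 0.8), c(1, 1), 0.5),
                 "AUROC undefined")
  expect_true(is.na(single@auroc))
  expect_error(kernelMetrics(c(0.2), c(1, 0)), "equal length")
})

test_that("metrics are invariant to input permutation", {
  set.seed(40)
  conf <- runif(50)
  lab <- rbinom(50, 1, 0.5)
  perm <- sample(50)
  a <- kernelMetrics(conf, lab, 0.4)
  b <- kernelMetrics(conf[perm], lab[perm], 0.4)
  expect_equal(metricsList(a), metricsList(b))
})

test_that("pixel metrics restrict to the annotated area", {
  tumor <- matrix(FALSE, 40, 40); tumor[1:20, 1:40] <- TRUE
  normal <- matrix(FALSE, 40, 40); normal[21:40, 1:40] <- TRUE
  gt <- makeMasks(tumor, normal)

  exact <- pixelMetrics(tumor, gt)
  expect_equal(exact@f1, 1)

  allTumor <- pixelMetrics(matrix(TRUE, 40, 40), gt)
  expect_equal(allTumor@recall, 1)
  expect_equal(allTumor@precision, 0.5)

  # unannotated pixels are excluded, not counted as negatives
  partial <- makeMasks(tumor, matrix(FALSE, 40, 40))
  onlyTumorGt <- pixelMetrics(matrix(TRUE, 40, 40), partial)
  expect_equal(onlyTumorGt@n, sum(tumor))
  expect_equal(onlyTumorGt@accuracy, 1)

  expect_error(pixelMetrics(matrix(TRUE, 10, 10), gt), "shapes differ")
  expect_error(pixelMetrics(matrix(TRUE, 40, 40),
                            makeMasks(matrix(FALSE, 40, 40),
                                      matrix(FALSE, 40, 40))),
               "empty annotated mask")
})

test_that("random pixel cases match a brute-force confusion count", {
  set.seed(41)
  for (rep in 1:4) {
    tumor <- matrix(runif(64 * 64) < 0.3, 64, 64)
    normal <- matrix(runif(64 * 64) < 0.3, 64, 64) & !tumor
    pred <- matrix(runif(64 * 64) < 0.5, 64, 64)
    rep1 <- pixelMetrics(pred, makeMasks(tumor, normal))
    tp <- fp <- fn <- tn <- 0L
    for (r in 1:64) for (c in 1:64) {
      if (tumor[r, c]) {
        if (pred[r, c]) tp <- tp + 1L else fn <- fn + 1L
      } else if (normal[r, c]) {
        if (pred[r, c]) fp <- fp + 1L else tn <- tn + 1L
      }
    }
    expect_equal(unname(as.vector(rep1@confusion)), c(tp, fp, fn, tn))
    expect_equal(rep1@accuracy, (tp + tn) / (tp + fp + fn + tn))
  }
})

test_that("ROC area equals trapezoid and concordant-pair computations", {
  expect_equal(rocCurve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auroc, 1)

  set.seed(42)
  confBig <- runif(4000)
  labBig <- sample(c(0, 1), 4000, replace = TRUE)
  expect_lt(abs(rocCurve(confBig, labBig)$auroc - 0.5), 0.05)

  # 6-point toy set against pair counting, plus an installed reference
  conf <- c(0.95, 0.7, 0.65, 0.4, 0.3, 0.1)
  lab <- c(1, 0, 1, 1, 0, 0)
  r <- rocCurve(conf, lab)
  expect_equal(r$auroc, bruteAuroc(conf, lab))
  expect_equal(r$auroc,
               as.numeric(pROC::auc(pROC::roc(lab, conf, quiet = TRUE,
                                              direction = "<"))))

  # small random sets with ties
  set.seed(43)
  for (rep in 1:10) {
    conf <- round(runif(10), 1)
    lab <- c(rep(1, 5), rep(0, 5))
    expect_equal(rocCurve(conf, lab)$auroc, bruteAuroc(conf, lab))
  }
  expect_error(rocCurve(c(0.5, 0.6), c(1, 1)), "both classes")
})

test_that("kernel and one-window pixel evaluations agree", {
  # each 128x128 slide is a single window; its pixel evaluation must match
  # the kernel evaluation of the same patches at the same threshold
  set.seed(44)
  n <- 8
  conf <- numeric(n)
  labels <- rep(c(1L, 0L), n / 2)
  masks <- vector("list", n)
  model <- meanModel()
  pixelPreds <- pixelTruth <- logical(0)
  for (k in seq_len(n)) {
    sl <- noiseSlide(128, 128, seed = 100 + k)
    conf[k] <- predictPatches(model, slidePixels(sl))
    seg <- segmentSlide(sl, model, step = 128L, threshold = 0.5)
    gt <- if (labels[k] == 1L)
      makeMasks(matrix(TRUE, 128, 128), matrix(FALSE, 128, 128))
    else
      makeMasks(matrix(FALSE, 128, 128), matrix(TRUE, 128, 128))
    pixelPreds <- c(pixelPreds, as.vector(tumorPixels(seg$mask)))
    pixelTruth <- c(pixelTruth, as.vector(tumorMask(gt)))
  }
  km <- kernelMetrics(conf, labels, 0.5)
  pm <- kernelMetrics(as.numeric(pixelPreds), as.numeric(pixelTruth), 0.5)
  expect_equal(km@accuracy, pm@accuracy)
  expect_equal(km@recall, pm@recall)
  expect_equal(km@precision, pm@precision)
})

test_that("macro-averaging reports mean and sd per metric", {
  a <- kernelMetrics(c(1, 1, 0, 0), c(1, 1, 0, 0), 0.5)
  b <- kernelMetrics(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0), 0.5)
  ma <- macroAverage(list(a, b))
  expect_equal(ma$mean[ma$metric == "f1"], mean(c(1, 0.5)))
  expect_equal(ma$sd[ma$metric == "f1"], sd(c(1, 0.5)))
  expect_true(all(ma$n == 2L))
})

test_that("metric reports serialize to JSON and CSV", {
  rep1 <- kernelMetrics(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0), 0.5)
  stem <- file.path(withr::local_tempdir(), "kernel")
  writeMetrics(rep1, stem)
  js <- jsonlite::fromJSON(paste0(stem, ".json"))
  expect_equal(js$f1, 0.5)
  cm <- read.csv(paste0(stem, "_confusion.csv"))
  expect_equal(cm$tumor, c(1, 1))
})
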