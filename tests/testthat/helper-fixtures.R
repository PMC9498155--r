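# Shared fixtures and independent oracles. Oracles deliberately use naive
# formulations (per-pixel loops, explicit grid scans, pair counting) that
# share no code path with the implementation they check.

# --- simple mock classifiers -------------------------------------------------

constantModel <- function(c) functionClassifier(function(tile) c)

# deterministic content-dependent mock: mean intensity scaled to [0, 1]
meanModel <- function() functionClassifier(function(tile) mean(tile) / 255)

# --- tiny raster builders ----------------------------------------------------

uniformSlide <- function(h, w, rgb, id = "slide") {
  px <- array(0, c(h, w, 3L))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  slideImage(px, slideId = id)
}

noiseSlide <- function(h, w, seed, id = "noise") {
  set.seed(seed)
  slideImage(array(sample(0:255, h * w * 3L, replace = TRUE),
                   c(h, w, 3L)), slideId = id)
}

rectPolygon <- function(r0, c0, r1, c1) {
  # integer-corner rectangle in (x, y) order; rasterizes to the inclusive
  # pixel range under the pixel-center, boundary-inclusive rule
  matrix(c(c0, r0, c1, r0, c1, r1, c0, r1), ncol = 2, byrow = TRUE)
}

# LabelMasks directly from logical matrices (bypasses rasterization)
makeMasks <- function(tumor, normal, tissue = NULL) {
  if (is.null(tissue)) tissue <- matrix(TRUE, nrow(tumor), ncol(tumor))
  new("LabelMasks", tumorMask = tumor, normalMask = normal,
      annotatedMask = tumor | normal, tissueMask = tissue)
}

# PatchSet from a 4D tile array and labels
makePatchSet <- function(tiles, labels, slideIds = NULL) {
  n <- dim(tiles)[4]
  if (is.null(slideIds)) slideIds <- rep("s", n)
  new("PatchSet", tiles = tiles,
      meta = data.frame(slideId = slideIds, row = 0L, col = 0L,
                        label = as.integer(labels), factor = 1L,
                        stringsAsFactors = FALSE),
      tileSize = dim(tiles)[1], splitTag = "unsplit")
}

# strongly separable two-texture tiles: class 0 bright, class 1 dark, both
# with additive noise
separableTiles <- function(n, size, seed) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), length.out = n)
  tiles <- array(0, c(size, size, 3L, n))
  for (k in seq_len(n)) {
    base <- if (labels[k] == 1L) 60 else 200
    tiles[, , , k] <- pmin(pmax(round(
      base + stats::rnorm(size * size * 3L, sd = 25)), 0), 255)
  }
  list(tiles = tiles, labels = labels)
}

# small classifier configuration for unit tests (same architecture family,
# smaller tiles so a training run takes seconds)
tinyConfig <- function(maxEpochs = 8L) {
  classifierConfig(tileSize = 64L, learningRate = 0.05, batchSize = 16L,
                   maxEpochs = maxEpochs, patience = 2L)
}

# the study conditions of the end-to-end recovery check: a 10-slide
# synthetic cohort at reduced slide size with well-separated textures
acceptanceSpec <- function(...)
  syntheticSlideSpec(height = 896L, width = 1280L, ...)

acceptanceTrainConfig <- function()
  classifierConfig(learningRate = 0.05, maxEpochs = 20L, batchSize = 32L,
                   patience = 3L)

cohortPatches <- function(cohort) {
  combinePatchSets(lapply(cohort, function(e) {
    masks <- rasterizeAnnotations(e$annotations, dim(e$slide)[1:2])
    extractPatches(e$slide, masks)
  }))
}

subsetBySlides <- function(patches, ids)
  patches[which(patchMeta(patches)$slideId %in% ids)]

# --- independent oracles -----------------------------------------------------

# even-odd point-in-polygon by scalar ray casting, one pixel at a time
bruteInsidePolygon <- function(x, y, rings) {
  crossings <- 0L
  for (ring in rings) {
    v <- ring
    n <- nrow(v)
    if (all(v[1, ] == v[n, ])) {
      v <- v[-n, , drop = FALSE]
      n <- n - 1L
    }
    for (e in seq_len(n)) {
      a <- v[e, ]; b <- v[if (e == n) 1L else e + 1L, ]
      if ((a[2] > y) != (b[2] > y)) {
        xi <- a[1] + (b[1] - a[1]) * (y - a[2]) / (b[2] - a[2])
        if (x < xi) crossings <- crossings + 1L
      }
    }
  }
  crossings %% 2L == 1L
}

bruteRasterize <- function(rings, h, w) {
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (c in seq_len(w))
    out[r, c] <- bruteInsidePolygon(c - 1L, r - 1L, rings)
  out
}

# anchors by naive enumeration with border clamping
bruteAnchors <- function(extent, window, step) {
  a <- unique(c(seq(0L, extent - window, by = step), extent - window))
  sort(a)
}

# mean-confidence map by row/column coverage algebra: an entirely different
# computational route (three matrix products) from the implementation's
# block accumulation
algebraicMap <- function(slide, model, window, step) {
  d <- dim(slide)[1:2]
  rows <- bruteAnchors(d[1], window, step)
  cols <- bruteAnchors(d[2], window, step)
  conf <- matrix(0, length(rows), length(cols))
  px <- slidePixels(slide)
  for (i in seq_along(rows)) for (j in seq_along(cols)) {
    tile <- px[rows[i] + seq_len(window), cols[j] + seq_len(window), ,
               drop = FALSE]
    dim(tile) <- c(window, window, 3L)
    conf[i, j] <- predictPatches(model, tile)
  }
  rowCov <- outer(seq_len(d[1]) - 1L, rows,
                  function(p, a) a <= p & p < a + window) * 1
  colCov <- outer(seq_len(d[2]) - 1L, cols,
                  function(p, a) a <= p & p < a + window) * 1
  sumMap <- rowCov %*% conf %*% t(colCov)
  cntMap <- rowCov %*% matrix(1, length(rows), length(cols)) %*% t(colCov)
  list(mean = sumMap / cntMap, count = cntMap)
}

# exhaustive threshold sweep oracle
bruteSweep <- function(confidences, labels, gridStep = 0.01) {
  grid <- seq(0, 1, by = gridStep)
  f1 <- sapply(grid, function(t) {
    pred <- as.integer(confidences >= t)
    tp <- sum(pred == 1 & labels == 1)
    fp <- sum(pred == 1 & labels == 0)
    fn <- sum(pred == 0 & labels == 1)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (p + r > 0) 2 * p * r / (p + r) else 0
  })
  list(grid = grid, f1 = f1, best = grid[which(f1 == max(f1))[1]],
       bestF1 = max(f1))
}

# AUROC as the concordant-pair (Mann-Whitney) statistic, ties counted half
bruteAuroc <- function(confidences, labels) {
  pos <- confidences[labels == 1]
  neg <- confidences[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}
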