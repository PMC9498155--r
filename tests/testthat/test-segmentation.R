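test_that("sliding anchors tile the image with border-flush extras", {
  expect_equal(slidingPositions(128, 128, 128, 128),
               cbind(row = 0L, col = 0L))
  p4 <- slidingPositions(256, 256, 128, 128)
  expect_equal(nrow(p4), 4L)

  # (200, 200, 128, 64): anchors equal brute-force enumeration with clamp
  p <- slidingPositions(200, 200, 128, 64)
  want <- bruteAnchors(200, 128, 64)
  expect_setequal(unique(p[, "row"]), want)
  expect_setequal(unique(p[, "col"]), want)

  # every pixel covered at least once, various extents and steps
  set.seed(3)
  for (rep in 1:6) {
    h <- sample(128:300, 1); w <- sample(128:300, 1)
    s <- sample(c(128, 64, 32, 16), 1)
    pos <- slidingPositions(h, w, 128, s)
    cov <- matrix(0L, h, w)
    for (k in seq_len(nrow(pos)))
      cov[pos[k, 1] + 1:128, pos[k, 2] + 1:128] <-
        cov[pos[k, 1] + 1:128, pos[k, 2] + 1:128] + 1L
    expect_true(all(cov >= 1L))
    # conservation: total coverage = window^2 x number of anchors
    expect_equal(sum(cov), 128^2 * nrow(pos))
  }
  expect_error(slidingPositions(100, 200, 128, 64), "window larger")
  expect_error(slidingPositions(200, 200, 128, 200), "step")
})

test_that("predictions per interior pixel match the stride-grid counts", {
  expect_equal(predictionsPerPixel(128, 128), 1L)
  expect_equal(predictionsPerPixel(128, 64), 4L)
  expect_equal(predictionsPerPixel(128, 32), 16L)
  expect_equal(predictionsPerPixel(128, 16), 64L)
  expect_equal(predictionsPerPixel(128, 8), 256L)
  for (s in c(1L, 2L, 4L, 8L, 16L))
    expect_equal(predictionsPerPixel(16L, s), (16L %/% s)^2)
  expect_error(predictionsPerPixel(128, 48), "divide")
})

test_that("constant models broadcast and are step-size independent", {
  sl <- noiseSlide(200, 260, seed = 11)
  segA <- segmentSlide(sl, constantModel(0.37), step = 64L,
                       threshold = 0.5)
  expect_true(all(abs(confidence(segA$map) - 0.37) < 1e-12))
  expect_false(any(tumorPixels(segA$mask)))
  segB <- segmentSlide(sl, constantModel(0.37), step = 32L,
                       threshold = 0.3)
  expect_equal(confidence(segB$map), confidence(segA$map))
  expect_true(all(tumorPixels(segB$mask)))

  one <- noiseSlide(128, 128, seed = 12)
  m <- meanModel()
  seg1 <- segmentSlide(one, m, step = 128L)
  want <- predictPatches(m, slidePixels(one))
  expect_true(all(abs(confidence(seg1$map) - want) < 1e-12))
  expect_true(all(coverage(seg1$map) == 1L))

  expect_error(segmentSlide(sl, buildClassifier(tinyConfig(), 1), 32L),
               "untrained")
})

test_that("aggregation equals the coverage-algebra oracle", {
  sl <- noiseSlide(300, 300, seed = 13)
  seg <- segmentSlide(sl, meanModel(), step = 32L, threshold = 0.5)
  oracle <- algebraicMap(sl, meanModel(), 128L, 32L)
  expect_lt(max(abs(confidence(seg$map) - oracle$mean)), 1e-9)
  expect_equal(coverage(seg$map), oracle$count,
               ignore_attr = TRUE)
  # interior coverage equals (window/step)^2
  interior <- coverage(seg$map)[150, 150]
  expect_equal(interior, predictionsPerPixel(128L, 32L))
})

test_that("raising the threshold never adds tumor pixels", {
  sl <- noiseSlide(220, 180, seed = 14)
  seg <- segmentSlide(sl, meanModel(), step = 64L, threshold = 0)
  prev <- binarizeMap(seg$map, 0)
  for (t in c(0.2, 0.4, 0.45, 0.5, 0.55, 0.8, 1)) {
    cur <- binarizeMap(seg$map, t)
    expect_true(all(tumorPixels(prev) | !tumorPixels(cur)))
    prev <- cur
  }
})

test_that("palettes render confidences as specified", {
  mk <- function(val) new("ConfidenceMap",
                          confidence = matrix(val, 4, 4),
                          coverage = matrix(1L, 4, 4),
                          window = 128L, step = 128L)
  expect_true(all(renderConfidence(mk(0), "grayscale") == 255))
  expect_true(all(renderConfidence(mk(1), "grayscale") == 0))
  half <- renderConfidence(mk(0.5), "grayscale")
  expect_true(all(half %in% c(127, 128)))
  expect_length(unique(as.vector(half)), 1L)

  lo <- renderConfidence(mk(0), "jet")
  hi <- renderConfidence(mk(1), "jet")
  expect_true(lo[1, 1, 3] > lo[1, 1, 1])   # blue end at 0
  expect_true(hi[1, 1, 1] > hi[1, 1, 3])   # red end at 1
  expect_equal(lo[1, 1, 1], 0)
  expect_equal(hi[1, 1, 3], 0)

  # uncovered pixels get the magenta sentinel
  partial <- mk(0.5)
  partial@coverage[1, 1] <- 0L
  partial@confidence[1, 1] <- -1
  img <- renderConfidence(partial, "grayscale")
  expect_equal(img[1, 1, ], c(255, 0, 255))
})

test_that("overlay tints exactly the mask support", {
  sl <- noiseSlide(40, 50, seed = 15)
  none <- matrix(FALSE, 40, 50)
  expect_equal(overlayMask(sl, none), slidePixels(sl))
  all <- matrix(TRUE, 40, 50)
  tinted <- overlayMask(sl, all)
  expect_false(any(tinted[, , 3] > slidePixels(sl)[, , 3]))
  rect <- none; rect[5:10, 6:12] <- TRUE
  ov <- overlayMask(sl, rect)
  for (ch in 1:3) {
    want <- slidePixels(sl)[, , ch]
    want[rect] <- round(0.55 * want[rect] + 0.45 * c(255, 255, 0)[ch])
    expect_equal(ov[, , ch], want)
  }
})

test_that("confidence maps round-trip through TIFF plus sidecar", {
  sl <- noiseSlide(140, 150, seed = 16)
  seg <- segmentSlide(sl, meanModel(), step = 64L)
  p <- withr::local_tempfile(fileext = ".tif")
  writeConfidenceMap(seg$map, p)
  back <- readConfidenceMap(p)
  expect_lt(max(abs(confidence(back) - confidence(seg$map))), 1e-6)
  expect_equal(coverage(back), coverage(seg$map))
})
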