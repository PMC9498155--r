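test_that("background masking follows the min-channel whiteness rule", {
  expect_false(any(maskBackground(uniformSlide(4, 5, c(255, 255, 255)))))
  expect_true(all(maskBackground(uniformSlide(4, 5, c(0, 0, 0)))))

  # synthetic slide with one tissue rectangle on white: mask equals the
  # rectangle, checked against per-pixel application of the rule
  px <- array(255, c(20, 30, 3L))
  px[5:12, 8:19, ] <- 120
  px[7, 9, ] <- c(250, 100, 240)   # one odd pixel: min channel below 220
  slide <- slideImage(px)
  got <- maskBackground(slide, 220)
  want <- matrix(NA, 20, 30)
  for (r in 1:20) for (c in 1:30)
    want[r, c] <- min(px[r, c, ]) < 220
  expect_identical(got, want)

  # background + tissue partition all pixels
  expect_true(all(xor(got, !got)))
  expect_error(maskBackground("x"), "SlideImage")
})

test_that("downsampling averages blocks with ceiling dimensions", {
  sl <- noiseSlide(8, 8, seed = 5)
  expect_identical(downsampleSlide(sl, 1L), sl)

  const <- uniformSlide(8, 8, c(37, 37, 37))
  d4 <- downsampleSlide(const, 4L)
  expect_equal(dim(d4), c(2L, 2L, 3L))
  expect_true(all(slidePixels(d4) == 37))
  expect_equal(downsampleFactor(d4), 4L)

  # 2x2 checkerboard of 0/255 -> single pixel at round(127.5) = 128
  px <- array(0, c(2, 2, 3L))
  px[1, 2, ] <- 255; px[2, 1, ] <- 255
  expect_true(all(slidePixels(downsampleSlide(slideImage(px), 2L)) == 128))

  # non-divisible extent: ceiling output, partial edge blocks averaged
  sl2 <- noiseSlide(7, 5, seed = 9)
  d2 <- downsampleSlide(sl2, 2L)
  expect_equal(dim(d2)[1:2], c(4L, 3L))
  pxs <- slidePixels(sl2)
  expect_equal(slidePixels(d2)[4, 3, 1], round(mean(pxs[7, 5, 1])))
  expect_equal(slidePixels(d2)[1, 1, 2], round(mean(pxs[1:2, 1:2, 2])))

  # composing factors keeps the dimensions of the product factor
  sl3 <- noiseSlide(24, 36, seed = 2)
  expect_equal(dim(downsampleSlide(downsampleSlide(sl3, 2L), 3L)),
               dim(downsampleSlide(sl3, 6L)))
  expect_error(downsampleSlide(sl3, 0L), "factor")
})

test_that("rasterization follows the pixel-center even-odd rule", {
  empty <- rasterizeAnnotations(annotationSet(), c(10, 10))
  expect_false(any(annotatedMask(empty)))

  ann <- annotationSet(list(rectPolygon(10, 10, 20, 20)), "tumor")
  masks <- rasterizeAnnotations(ann, c(30, 30))
  brute <- bruteRasterize(list(rectPolygon(10, 10, 20, 20)), 30, 30)
  # boundary pixels are included by contract; the strict-interior oracle
  # must agree everywhere off the boundary, and the total count equals the
  # inclusive 11 x 11 square
  expect_equal(sum(tumorMask(masks)), 11 * 11)
  expect_true(all(tumorMask(masks)[brute]))

  two <- annotationSet(list(rectPolygon(1, 1, 8, 8),
                            rectPolygon(12, 12, 18, 18)),
                       c("tumor", "normal"))
  m2 <- rasterizeAnnotations(two, c(25, 25))
  expect_false(any(tumorMask(m2) & normalMask(m2)))
  expect_identical(annotatedMask(m2), tumorMask(m2) | normalMask(m2))

  # masks independent of region ordering
  rev2 <- annotationSet(list(rectPolygon(12, 12, 18, 18),
                             rectPolygon(1, 1, 8, 8)),
                        c("normal", "tumor"))
  mrev <- rasterizeAnnotations(rev2, c(25, 25))
  expect_identical(tumorMask(m2), tumorMask(mrev))
  expect_identical(normalMask(m2), normalMask(mrev))

  overlapping <- annotationSet(list(rectPolygon(1, 1, 10, 10),
                                    rectPolygon(5, 5, 15, 15)),
                               c("tumor", "normal"))
  expect_error(rasterizeAnnotations(overlapping, c(20, 20)),
               "overlap.*\\(1, 2\\)")
})

test_that("rasterization matches the even-odd oracle on random polygons", {
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(3:7, 1)
    pts <- cbind(runif(n, 0.5, 24.5), runif(n, 0.5, 24.5))
    hull <- pts[grDevices::chull(pts), , drop = FALSE]
    if (nrow(hull) < 3) next
    ann <- annotationSet(list(hull), "tumor")
    got <- tumorMask(rasterizeAnnotations(ann, c(25, 25)))
    want <- bruteRasterize(list(hull), 25, 25)
    expect_identical(got, want)
  }
})

test_that("polygon holes are excluded from the mask", {
  outer <- rectPolygon(0, 0, 20, 20)
  hole <- rectPolygon(5, 5, 10, 10)
  ann <- annotationSet(list(list(outer, hole)), "tumor")
  m <- tumorMask(rasterizeAnnotations(ann, c(25, 25)))
  expect_false(m[8 + 1, 8 + 1])        # strictly inside the hole
  expect_true(m[15 + 1, 15 + 1])       # inside outer, outside hole
  # hole pixels on the interior-ring edge are boundary, hence included by
  # contract; only the 4 x 4 strict interior of the hole is excluded
  expect_equal(sum(m), 21 * 21 - 4 * 4)
  # every pixel the strict even-odd oracle marks inside is in the mask
  expect_true(all(m[bruteRasterize(list(outer, hole), 25, 25)]))
})

test_that("GeoJSON annotations round-trip and reject unknown classes", {
  ann <- annotationSet(list(rectPolygon(2, 3, 9, 14),
                            list(rectPolygon(20, 20, 40, 40),
                                 rectPolygon(25, 25, 30, 30))),
                       c("tumor", "normal"))
  path <- withr::local_tempfile(fileext = ".geojson")
  writeAnnotations(ann, path)
  back <- readAnnotations(path)
  expect_equal(regionLabels(back), regionLabels(ann))
  for (i in seq_along(regionPolygons(ann)))
    for (j in seq_along(regionPolygons(ann)[[i]]))
      expect_equal(unname(regionPolygons(back)[[i]][[j]]),
                   unname(regionPolygons(ann)[[i]][[j]]))

  noClass <- list(type = "FeatureCollection", features = list(list(
    type = "Feature",
    geometry = list(type = "Polygon",
                    coordinates = list(list(c(0, 0), c(5, 0), c(5, 5),
                                            c(0, 0)))),
    properties = list())))
  badPath <- withr::local_tempfile(fileext = ".geojson")
  writeLines(jsonlite::toJSON(noClass, auto_unbox = TRUE), badPath)
  expect_error(readAnnotations(badPath), "classification")

  wrongClass <- noClass
  wrongClass$features[[1]]$properties <-
    list(classification = list(name = "Stroma"))
  writeLines(jsonlite::toJSON(wrongClass, auto_unbox = TRUE), badPath)
  expect_error(readAnnotations(badPath), "unknown annotation class")
})

test_that("slide and mask rasters round-trip through PNG and TIFF", {
  sl <- noiseSlide(13, 17, seed = 3, id = "rt")
  for (ext in c(".png", ".tif")) {
    p <- withr::local_tempfile(fileext = ext)
    writeSlide(sl, p)
    back <- readSlide(p)
    expect_equal(slidePixels(back), slidePixels(sl))
  }
  m <- matrix(c(TRUE, FALSE), 6, 8)
  mp <- withr::local_tempfile(fileext = ".png")
  writeMask(m, mp)
  expect_identical(readMask(mp), m)
})
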