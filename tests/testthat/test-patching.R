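test_that("tile extraction emits only fully-inside grid tiles", {
  sl <- noiseSlide(256, 256, seed = 1)
  allTumor <- makeMasks(matrix(TRUE, 256, 256), matrix(FALSE, 256, 256))
  ps <- extractPatches(sl, allTumor)
  expect_equal(length(ps), 4L)
  expect_true(all(patchLabels(ps) == 1L))
  expect_setequal(paste(patchMeta(ps)$row, patchMeta(ps)$col),
                  c("0 0", "0 128", "128 0", "128 128"))
  # tiles carry the actual pixels
  expect_equal(patchTiles(ps)[, , , 1],
               slidePixels(sl)[1:128, 1:128, ])

  # annotated region smaller than a tile yields nothing
  small <- matrix(FALSE, 256, 256)
  small[10:109, 10:109] <- TRUE
  expect_equal(length(extractPatches(sl, makeMasks(small,
                                                   matrix(FALSE, 256, 256)))),
               0L)

  # tile larger than the image: empty dataset, not an error
  tiny <- noiseSlide(64, 64, seed = 2)
  expect_equal(length(extractPatches(tiny,
                                     makeMasks(matrix(TRUE, 64, 64),
                                               matrix(FALSE, 64, 64)))), 0L)
})

test_that("extraction count matches an exhaustive grid-scan oracle", {
  set.seed(77)
  for (rep in 1:5) {
    h <- sample(320:420, 1); w <- sample(300:400, 1)
    tumor <- matrix(FALSE, h, w)
    normal <- matrix(FALSE, h, w)
    # random rectangular blobs per class, kept disjoint by row bands
    tumor[sample(1:20, 1) + 0:149, sample(1:(w - 160), 1) + 0:149] <- TRUE
    normal[sample(175:(h - 130), 1) + 0:129,
           sample(1:(w - 140), 1) + 0:129] <- TRUE
    sl <- noiseSlide(h, w, seed = rep)
    ps <- extractPatches(sl, makeMasks(tumor, normal), 128L, 128L)

    want <- 0L
    for (r0 in seq(0, h - 128, by = 128)) for (c0 in seq(0, w - 128, by = 128)) {
      tb <- tumor[r0 + 1:128, c0 + 1:128]
      nb <- normal[r0 + 1:128, c0 + 1:128]
      if (all(tb) || all(nb)) want <- want + 1L
    }
    expect_equal(length(ps), want)

    # no emitted patch crosses the annotated-region boundary
    for (k in seq_len(length(ps))) {
      r0 <- patchMeta(ps)$row[k]; c0 <- patchMeta(ps)$col[k]
      mask <- if (patchMeta(ps)$label[k] == 1L) tumor else normal
      expect_true(all(mask[r0 + 1:128, c0 + 1:128]))
    }
    # deterministic
    expect_equal(patchMeta(extractPatches(sl, makeMasks(tumor, normal))),
                 patchMeta(ps))
  }
})

test_that("class balancing undersamples the majority deterministically", {
  tiles <- array(seq_len(8 * 8 * 3 * 15), c(8, 8, 3, 15))
  ps <- makePatchSet(tiles, c(rep(1, 10), rep(0, 5)))
  ps@tileSize <- 8L
  bal <- balanceClasses(ps, seed = 4)
  expect_equal(sum(patchLabels(bal) == 1), 5L)
  expect_equal(sum(patchLabels(bal) == 0), 5L)
  expect_equal(patchMeta(balanceClasses(ps, seed = 4)),
               patchMeta(bal))

  even <- makePatchSet(tiles[, , , 1:6, drop = FALSE], c(1, 0, 1, 0, 1, 0))
  even@tileSize <- 8L
  expect_equal(length(balanceClasses(even, seed = 1)), 6L)

  oneClass <- makePatchSet(tiles[, , , 1:4, drop = FALSE], rep(1, 4))
  oneClass@tileSize <- 8L
  expect_error(balanceClasses(oneClass, seed = 1), "normal class is empty")
})

test_that("slide-level split honors fractions and partitions the ids", {
  ids <- sprintf("s%02d", 1:10)
  sp <- splitSlides(ids, seed = 5)
  expect_equal(lengths(sp), c(train = 7L, validation = 1L, test = 2L))
  expect_setequal(unlist(sp), ids)
  expect_equal(splitSlides(ids, seed = 5), sp)
  expect_false(identical(splitSlides(ids, seed = 6)$train, sp$train))

  expect_warning(one <- splitSlides("only", seed = 1), "too few")
  expect_equal(one$train, "only")
  expect_equal(length(one$validation) + length(one$test), 0L)

  expect_error(splitSlides(c("a", "a"), seed = 1), "unique")
  expect_error(splitSlides(ids, fractions = c(0.5, 0.2, 0.2), seed = 1),
               "summing to 1")
})

test_that("patch sets persist as PNG tiles plus a CSV manifest", {
  fix <- separableTiles(6, 16, seed = 8)
  ps <- makePatchSet(fix$tiles, fix$labels,
                     slideIds = rep(c("a", "b"), 3))
  ps@tileSize <- 16L
  dir <- withr::local_tempdir()
  writePatchSet(ps, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- readPatchSet(dir)
  expect_equal(patchTiles(back), patchTiles(ps))
  expect_equal(patchMeta(back), patchMeta(ps))
})
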