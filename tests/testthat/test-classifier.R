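# Unit-level checks run on 64-pixel tiles: same four-layer architecture,
# seconds-scale training. The full 128-pixel study conditions are exercised
# in test-acceptance.R.

test_that("the untrained network already satisfies the prediction contract", {
  cfg <- tinyConfig()
  model <- buildClassifier(cfg, seed = 3)
  set.seed(10)
  tiles <- array(sample(0:255, 64 * 64 * 3 * 5, replace = TRUE),
                 c(64, 64, 3, 5))
  conf <- predictPatches(model, tiles)
  expect_length(conf, 5L)
  expect_true(all(conf >= 0 & conf <= 1))

  # same seed -> identical weights -> identical outputs
  model2 <- buildClassifier(cfg, seed = 3)
  expect_identical(predictPatches(model2, tiles), conf)
  expect_false(identical(predictPatches(buildClassifier(cfg, seed = 4),
                                        tiles), conf))

  # batched evaluation equals one-by-one evaluation
  oneByOne <- vapply(1:5, function(k)
    predictPatches(model, tiles[, , , k]), numeric(1))
  expect_equal(conf, oneByOne, tolerance = 1e-6)

  # k copies of one tile give k identical confidences
  copies <- tiles[, , , rep(1L, 4L), drop = FALSE]
  expect_equal(predictPatches(model, copies), rep(conf[1], 4))

  expect_identical(predictPatches(model, array(0, c(64, 64, 3, 0))),
                   numeric(0))
  expect_error(predictPatches(model, array(0, c(32, 32, 3, 1))),
               "expected 64 x 64 x 3")
})

test_that("configuration validation rejects degenerate hyperparameters", {
  expect_error(classifierConfig(convFilters = c(8L, 16L)), "length 4")
  expect_error(classifierConfig(learningRate = 0), "positive")
  expect_error(classifierConfig(momentum = -0.1), "non-negative")
})

test_that("training separates two textures and applies early stopping", {
  fix <- separableTiles(40, 64, seed = 21)
  ps <- makePatchSet(fix$tiles, fix$labels)
  cfg <- tinyConfig()
  model <- buildClassifier(cfg, seed = 1)
  trained <- trainClassifier(model, ps, cfg, seed = 2)
  hist <- trainingHistory(trained)

  expect_true(isTrained(trained))
  expect_gte(nrow(hist), 1L)
  expect_lte(nrow(hist), cfg$maxEpochs)
  # restored weights are those of the minimum-validation-loss epoch
  expect_equal(bestEpoch(trained), which.min(hist$valLoss))
  expect_true(all(hist$valLoss[bestEpoch(trained)] <= hist$valLoss))

  # holdout-style accuracy on fresh tiles from the same textures
  fresh <- separableTiles(20, 64, seed = 22)
  conf <- predictPatches(trained, fresh$tiles)
  acc <- mean(as.integer(conf >= 0.5) == fresh$labels)
  expect_gte(acc, 0.95)

  # training is deterministic: bit-identical history on a repeated run
  again <- trainClassifier(buildClassifier(cfg, seed = 1), ps, cfg,
                           seed = 2)
  expect_identical(trainingHistory(again), hist)
  expect_identical(predictPatches(again, fresh$tiles), conf)

  oneClass <- makePatchSet(fix$tiles[, , , fix$labels == 1, drop = FALSE],
                           fix$labels[fix$labels == 1])
  expect_error(trainClassifier(model, oneClass, cfg, seed = 1),
               "both classes")
})

test_that("classifiers persist with config sidecar and training log", {
  fix <- separableTiles(24, 64, seed = 30)
  cfg <- tinyConfig(maxEpochs = 3L)
  trained <- trainClassifier(buildClassifier(cfg, seed = 1),
                             makePatchSet(fix$tiles, fix$labels), cfg,
                             seed = 2)
  dir <- withr::local_tempdir()
  writeClassifier(trained, dir)
  expect_true(all(file.exists(file.path(dir, c("model.rds", "config.json",
                                               "history.csv")))))
  back <- readClassifier(dir)
  tiles <- fix$tiles[, , , 1:3, drop = FALSE]
  expect_identical(predictPatches(back, tiles),
                   predictPatches(trained, tiles))
  sidecar <- jsonlite::fromJSON(file.path(dir, "config.json"))
  expect_equal(sidecar$learningRate, cfg$learningRate)
})
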