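#' @include AllClasses.R AllGenerics.R cnn.R utils.R
NULL

#' Hyperparameter set of the compact patch classifier
#'
#' Defaults are the reference training setup of the segmentation method
#' this package implements: four convolutions with filter counts 8/16/16/32 and kernels
#' 3x3, 3x3, 5x5, 3x3, SELU activations, per-layer batch normalization, a
#' 2-unit softmax head fed by global average pooling, SGD with momentum 0.75
#' and learning rate 1e-4, L2 weight decay, mean-squared-error loss on the
#' softmax tumor probability against the 0/1 label, batch size 64 and
#' early stopping on validation loss. The learning rate and epoch budget
#' were tuned for slide databases of hundreds of thousands of patches; at
#' desk scale (hundreds of patches) raise `learningRate` and `maxEpochs` so
#' that a comparable number of weight updates is performed.
#'
#' @param tileSize input tile side in pixels.
#' @param convFilters,convKernels integer vectors of length 4.
#' @param learningRate,momentum SGD parameters.
#' @param weightDecay L2 penalty coefficient on weight matrices.
#' @param batchSize mini-batch size.
#' @param maxEpochs upper bound on training epochs.
#' @param patience epochs without validation-loss improvement before
#'   stopping.
#' @param bnMomentum,bnEps batch-norm running-average momentum and variance
#'   floor.
#' @return named list of hyperparameters.
#' @export
classifierConfig <- function(tileSize = 128L,
                             convFilters = c(8L, 16L, 16L, 32L),
                             convKernels = c(3L, 3L, 5L, 3L),
                             learningRate = 1e-4,
                             momentum = 0.75,
                             weightDecay = 1e-4,
                             batchSize = 64L,
                             maxEpochs = 30L,
                             patience = 2L,
                             bnMomentum = 0.9,
                             bnEps = 1e-5) {
  config <- list(tileSize = asIntegerStrict(tileSize, "tileSize"),
                 convFilters = asIntegerStrict(convFilters, "convFilters"),
                 convKernels = asIntegerStrict(convKernels, "convKernels"),
                 learningRate = learningRate, momentum = momentum,
                 weightDecay = weightDecay,
                 batchSize = asIntegerStrict(batchSize, "batchSize"),
                 maxEpochs = asIntegerStrict(maxEpochs, "maxEpochs"),
                 patience = asIntegerStrict(patience, "patience"),
                 bnMomentum = bnMomentum, bnEps = bnEps)
  if (length(config$convFilters) != 4L || length(config$convKernels) != 4L)
    stop("convFilters and convKernels must have length 4")
  for (nm in c("learningRate", "batchSize", "maxEpochs", "patience"))
    if (config[[nm]] <= 0) stop(sprintf("%s must be positive", nm))
  for (nm in c("momentum", "weightDecay"))
    if (config[[nm]] < 0) stop(sprintf("%s must be non-negative", nm))
  config
}

#' Build an (untrained) patch classifier
#'
#' Initializes the network weights deterministically from `seed` (LeCun
#' normal, the standard pairing with SELU). The untrained model already
#' satisfies the prediction contract — confidences in `[0, 1]` — but carries
#' no learned structure until [trainClassifier()] is run.
#'
#' @param config list from [classifierConfig()].
#' @param seed integer RNG seed for weight initialization.
#' @return a [TumorClassifier-class].
#' @export
buildClassifier <- function(config = classifierConfig(), seed = 1L) {
  new("TumorClassifier",
      config = config,
      params = cnnInitParams(config, seed),
      state = cnnInitState(config),
      trained = FALSE)
}

#' Train the patch classifier with early stopping
#'
#' Splits off `holdoutFraction` of the patches (stratified by class) as the
#' epoch-level validation set, runs SGD with momentum over shuffled
#' mini-batches, and stops once the validation loss has not improved for
#' `config$patience` consecutive epochs. The returned model carries the
#' weights of the best (minimum validation loss) epoch.
#'
#' @param model an untrained or trained [TumorClassifier-class].
#' @param trainSet a [PatchSet-class] with both classes present (balance
#'   first with [balanceClasses()]).
#' @param config hyperparameters; defaults to the model's own.
#' @param holdoutFraction fraction of patches held out for epoch validation.
#' @param seed integer seed driving the holdout split and batch shuffling.
#' @return the trained [TumorClassifier-class]; its `history` slot holds the
#'   per-epoch train/validation losses and `bestEpoch` the restored epoch.
#' @export
trainClassifier <- function(model, trainSet, config = model@config,
                            holdoutFraction = 0.10, seed = 1L) {
  if (!is(model, "TumorClassifier")) stop("model must be a TumorClassifier")
  if (!is(trainSet, "PatchSet")) stop("trainSet must be a PatchSet")
  labels <- patchLabels(trainSet)
  if (length(unique(labels)) < 2L)
    stop("training requires both classes; got a single-class dataset")
  n <- length(trainSet)
  idxT <- which(labels == 1); idxN <- which(labels == 0)
  holdout <- withSeed(seed, {
    c(sample(idxT, max(1L, round(holdoutFraction * length(idxT)))),
      sample(idxN, max(1L, round(holdoutFraction * length(idxN)))))
  })
  trainIdx <- setdiff(seq_len(n), holdout)
  tiles <- patchTiles(trainSet)
  valTiles <- tiles[, , , holdout, drop = FALSE]
  valLabels <- labels[holdout]
  geom <- cnnGeometry(config)
  params <- model@params
  state <- model@state
  velocity <- cnnZeroVelocity(params)
  epochSeeds <- deriveSeeds(seed + 1L, config$maxEpochs)
  history <- data.frame(epoch = integer(), trainLoss = numeric(),
                        valLoss = numeric())
  best <- list(loss = Inf, params = params, state = state, epoch = 0L)
  stall <- 0L
  for (epoch in seq_len(config$maxEpochs)) {
    order <- withSeed(epochSeeds[epoch], sample(trainIdx))
    lossSum <- 0
    for (start in seq(1L, length(order), by = config$batchSize)) {
      batch <- order[start:min(start + config$batchSize - 1L,
                               length(order))]
      bt <- tiles[, , , batch, drop = FALSE]
      fwd <- cnnForward(params, state, config, bt, training = TRUE,
                        geom = geom)
      state <- fwd$state
      lossSum <- lossSum + sum((fwd$conf - labels[batch])^2)
      grads <- cnnBackward(params, config, fwd, labels[batch], geom = geom)
      upd <- cnnUpdate(params, grads, velocity, config)
      params <- upd$params
      velocity <- upd$velocity
    }
    valConf <- cnnPredictBatched(params, state, config, valTiles,
                                 config$batchSize, geom)
    valLoss <- mean((valConf - valLabels)^2)
    history <- rbind(history, data.frame(
      epoch = epoch, trainLoss = lossSum / length(order),
      valLoss = valLoss))
    if (valLoss < best$loss - 1e-12) {
      best <- list(loss = valLoss, params = params, state = state,
                   epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  initialize(model, config = config, params = best$params,
             state = best$state, trained = TRUE, history = history,
             bestEpoch = as.integer(best$epoch))
}

cnnPredictBatched <- function(params, state, config, tiles, batchSize,
                              geom = cnnGeometry(config)) {
  n <- dim(tiles)[4]
  if (n == 0L) return(numeric(0))
  out <- numeric(n)
  for (start in seq(1L, n, by = batchSize)) {
    take <- start:min(start + batchSize - 1L, n)
    out[take] <- cnnForward(params, state, config,
                            tiles[, , , take, drop = FALSE],
                            training = FALSE, geom = geom)$conf
  }
  out
}

normalizeTiles <- function(tiles, tileSize) {
  if (is(tiles, "PatchSet")) tiles <- patchTiles(tiles)
  d <- dim(tiles)
  if (length(d) == 3L) {
    dim(tiles) <- c(d, 1L)
    d <- dim(tiles)
  }
  if (length(d) != 4L || d[1] != tileSize || d[2] != tileSize || d[3] != 3L)
    stop(sprintf("expected %d x %d x 3 tiles, got shape (%s)",
                 tileSize, tileSize, paste(d, collapse = ", ")))
  tiles
}

#' @rdname predictPatches
#' @export
setMethod("predictPatches", "TumorClassifier",
  function(object, tiles, batchSize = 64L) {
    tiles <- normalizeTiles(tiles, object@config$tileSize)
    cnnPredictBatched(object@params, object@state, object@config, tiles,
                      batchSize)
  })

#' @rdname predictPatches
#' @export
setMethod("predictPatches", "FunctionClassifier",
  function(object, tiles, batchSize = 64L) {
    if (is(tiles, "PatchSet")) tiles <- patchTiles(tiles)
    d <- dim(tiles)
    if (length(d) == 3L) dim(tiles) <- c(d, 1L)
    n <- dim(tiles)[4]
    vapply(seq_len(n),
           function(k) object@fn(tiles[, , , k, drop = TRUE]),
           numeric(1))
  })

#' Wrap a tile-scoring function as a classifier
#'
#' @param fn function mapping one `s x s x 3` tile to a confidence in
#'   `[0, 1]`.
#' @return a [FunctionClassifier-class] usable wherever a trained model is
#'   accepted.
#' @export
functionClassifier <- function(fn) new("FunctionClassifier", fn = fn)

#' Persist / load a trained classifier
#'
#' The weights go to `model.rds`; a JSON sidecar (`config.json`) records the
#' full hyperparameter set and the training log is written to
#' `history.csv`.
#'
#' @param model a [TumorClassifier-class].
#' @param dir output directory.
#' @return `readClassifier` returns the [TumorClassifier-class].
#' @export
writeClassifier <- function(model, dir) {
  if (!is(model, "TumorClassifier")) stop("model must be a TumorClassifier")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "model.rds"))
  writeLines(jsonlite::toJSON(model@config, auto_unbox = TRUE, digits = NA),
             file.path(dir, "config.json"))
  utils::write.csv(model@history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname writeClassifier
#' @export
readClassifier <- function(dir) readRDS(file.path(dir, "model.rds"))
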