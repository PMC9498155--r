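# Internal convolutional-network engine.
#
# Layout conventions: a batch of tiles is an (H, W, C, N) array; flattening
# the first three dimensions gives the column-major linear index
# r + (c-1)*H + (ch-1)*H*W used by the im2col index tables, so every
# convolution is one GEMM per layer over the whole batch. Batch norm
# operates per channel (rows of the F x (P*N) response matrix), SELU is
# elementwise, max pooling is 2x2/stride 2 with argmax routing for the
# backward pass, and the head is global average pooling into a 2-unit
# softmax whose tumor probability feeds a mean-squared-error loss.

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

selu <- function(x) SELU_LAMBDA * ifelse(x > 0, x, SELU_ALPHA * expm1(x))

# Derivative expressed through the cached output (out = selu(x)):
# lambda for x > 0, out + lambda*alpha otherwise.
seluDerivFromOut <- function(x, out)
  ifelse(x > 0, SELU_LAMBDA, out + SELU_LAMBDA * SELU_ALPHA)

# Per-layer geometry: im2col index tables and pooling index vectors.
cnnGeometry <- function(config) {
  inH <- config$tileSize; inW <- config$tileSize; inC <- 3L
  layers <- vector("list", length(config$convFilters))
  for (l in seq_along(layers)) {
    k <- config$convKernels[l]; f <- config$convFilters[l]
    outH <- inH - k + 1L; outW <- inW - k + 1L
    if (outH < 2L || outW < 2L)
      stop("tile too small for the configured architecture")
    K <- k * k * inC; P <- outH * outW
    dr <- rep(seq_len(k), times = k * inC)
    dc <- rep(rep(seq_len(k), each = k), times = inC)
    ch <- rep(seq_len(inC), each = k * k)
    offK <- dr + (dc - 1L) * inH + (ch - 1L) * inH * inW
    i <- rep(seq_len(outH), times = outW)
    j <- rep(seq_len(outW), each = outH)
    baseP <- (i - 1L) + (j - 1L) * inH
    idx <- outer(offK, baseP, "+")          # K x P
    ph <- outH %/% 2L; pw <- outW %/% 2L
    us <- rep(seq_len(ph), times = pw)
    vs <- rep(seq_len(pw), each = ph)
    q <- lapply(1:4, function(o) {
      a <- (o - 1L) %% 2L + 1L; b <- (o - 1L) %/% 2L + 1L
      (2L * us - 2L + a) + (2L * vs - 2L + b - 1L) * outH
    })
    layers[[l]] <- list(k = k, f = f, inC = inC, inH = inH, inW = inW,
                        outH = outH, outW = outW, K = K, P = P,
                        idx = as.vector(idx), q = q, ph = ph, pw = pw)
    inH <- ph; inW <- pw; inC <- f
  }
  list(layers = layers, featDim = inC, featSpatial = inH * inW)
}

cnnInitParams <- function(config, seed) {
  geom <- cnnGeometry(config)
  withSeed(seed, {
    params <- list(W = list(), b = list(), gamma = list(), beta = list())
    for (l in seq_along(geom$layers)) {
      g <- geom$layers[[l]]
      # LeCun normal initialization, the standard pairing with SELU
      params$W[[l]] <- matrix(stats::rnorm(g$f * g$K, sd = sqrt(1 / g$K)),
                              g$f, g$K)
      params$b[[l]] <- numeric(g$f)
      params$gamma[[l]] <- rep(1, g$f)
      params$beta[[l]] <- numeric(g$f)
    }
    params$Wd <- matrix(stats::rnorm(2L * geom$featDim,
                                     sd = sqrt(1 / geom$featDim)),
                        2L, geom$featDim)
    params$bd <- numeric(2L)
    params
  })
}

cnnInitState <- function(config) {
  geom <- cnnGeometry(config)
  # running stats are bias-corrected exponential averages (division by
  # 1 - momentum^t at read time), so inference is unbiased even after few
  # batches
  list(runMean = lapply(geom$layers, function(g) numeric(g$f)),
       runVar = lapply(geom$layers, function(g) numeric(g$f)),
       steps = 0L)
}

# Forward pass over a batch. `tiles`: (s, s, 3, N) array of raw 8-bit
# intensities (scaled to [0, 1] here). Returns confidences and, when
# training, the caches needed by cnnBackward plus updated running stats.
cnnForward <- function(params, state, config, tiles, training = FALSE,
                       geom = cnnGeometry(config)) {
  d <- dim(tiles)
  if (length(d) != 4L || d[1] != config$tileSize || d[2] != config$tileSize ||
      d[3] != 3L)
    stop(sprintf("tiles must be %d x %d x 3 x N",
                 config$tileSize, config$tileSize))
  n <- d[4]
  eps <- config$bnEps
  a <- tiles / 255
  dim(a) <- c(d[1] * d[2] * 3L, n)
  caches <- if (training) vector("list", length(geom$layers))
  for (l in seq_along(geom$layers)) {
    g <- geom$layers[[l]]
    x <- a[g$idx, , drop = FALSE]
    dim(x) <- c(g$K, g$P * n)
    z <- params$W[[l]] %*% x + params$b[[l]]
    if (training) {
      mu <- rowMeans(z)
      va <- rowMeans(z * z) - mu * mu
      state$runMean[[l]] <- config$bnMomentum * state$runMean[[l]] +
        (1 - config$bnMomentum) * mu
      state$runVar[[l]] <- config$bnMomentum * state$runVar[[l]] +
        (1 - config$bnMomentum) * va
      if (l == length(geom$layers)) state$steps <- state$steps + 1L
    } else if (state$steps == 0L) {
      mu <- numeric(length(state$runMean[[l]]))
      va <- rep(1, length(mu))
    } else {
      corr <- 1 - config$bnMomentum^state$steps
      mu <- state$runMean[[l]] / corr
      va <- state$runVar[[l]] / corr
    }
    sdv <- sqrt(va + eps)
    zh <- (z - mu) / sdv
    y <- params$gamma[[l]] * zh + params$beta[[l]]
    act <- selu(y)
    dim(act) <- c(g$f, g$P, n)
    a1 <- act[, g$q[[1]], , drop = FALSE]
    a2 <- act[, g$q[[2]], , drop = FALSE]
    a3 <- act[, g$q[[3]], , drop = FALSE]
    a4 <- act[, g$q[[4]], , drop = FALSE]
    m <- pmax(a1, a2, a3, a4)
    if (training) {
      w1 <- a1 == m
      w2 <- (a2 == m) & !w1
      w3 <- (a3 == m) & !(w1 | w2)
      w4 <- (a4 == m) & !(w1 | w2 | w3)
      caches[[l]] <- list(x = x, zh = zh, sdv = sdv, y = y, act = act,
                          masks = list(w1, w2, w3, w4))
    }
    a <- aperm(m, c(2, 1, 3))                # (Pp, F, N): spatial-major
    dim(a) <- c(g$ph * g$pw * g$f, n)
  }
  # global average pooling over the last pooled spatial grid
  gl <- geom$layers[[length(geom$layers)]]
  dim(a) <- c(geom$featSpatial, geom$featDim, n)
  feat <- colSums(a, dims = 1) / geom$featSpatial   # featDim x N
  if (n == 1L) feat <- matrix(feat, ncol = 1L)
  zd <- params$Wd %*% feat + params$bd
  zd <- zd - rep(apply(zd, 2, max), each = 2L)
  ez <- exp(zd)
  prob <- ez / rep(colSums(ez), each = 2L)
  conf <- prob[2L, ]
  if (!training) return(list(conf = conf))
  list(conf = conf, prob = prob, feat = feat, caches = caches, n = n,
       state = state)
}

# Backward pass; returns gradients matching the params structure.
cnnBackward <- function(params, config, fwd, labels,
                        geom = cnnGeometry(config)) {
  n <- fwd$n
  conf <- fwd$conf
  # d(MSE)/d(conf), then through the two-logit softmax
  dconf <- 2 * (conf - labels) / n
  dzt <- dconf * conf * (1 - conf)
  dzd <- rbind(-dzt, dzt)
  grads <- list(W = vector("list", length(geom$layers)),
                b = vector("list", length(geom$layers)),
                gamma = vector("list", length(geom$layers)),
                beta = vector("list", length(geom$layers)))
  grads$Wd <- dzd %*% t(fwd$feat)
  grads$bd <- rowSums(dzd)
  dfeat <- crossprod(params$Wd, dzd)          # featDim x N
  # undo GAP: spread evenly over the last spatial grid
  tmp <- dfeat / geom$featSpatial
  da <- aperm(array(tmp, c(geom$featDim, n, geom$featSpatial)), c(3, 1, 2))
  dim(da) <- c(geom$featSpatial * geom$featDim, n)
  for (l in rev(seq_along(geom$layers))) {
    g <- geom$layers[[l]]
    cache <- fwd$caches[[l]]
    dim(da) <- c(g$ph * g$pw, g$f, n)
    dm <- aperm(da, c(2, 1, 3))               # (F, Pp, N)
    dact <- array(0, c(g$f, g$P, n))
    for (o in 1:4)
      dact[, g$q[[o]], ] <- dm * cache$masks[[o]]
    dim(dact) <- c(g$f, g$P * n)
    dy <- dact * seluDerivFromOut(cache$y, matrix(cache$act,
                                                  g$f, g$P * n))
    dzh <- dy * params$gamma[[l]]
    grads$gamma[[l]] <- rowSums(dy * cache$zh)
    grads$beta[[l]] <- rowSums(dy)
    dz <- (dzh - rowMeans(dzh) - cache$zh * rowMeans(dzh * cache$zh)) /
      cache$sdv
    grads$W[[l]] <- dz %*% t(cache$x)
    grads$b[[l]] <- rowSums(dz)
    dx <- crossprod(params$W[[l]], dz)        # K x (P*N)
    dim(dx) <- c(g$K * g$P, n)
    acc <- rowsum(dx, g$idx)
    da <- matrix(0, g$inH * g$inW * g$inC, n)
    da[as.integer(rownames(acc)), ] <- acc
  }
  grads
}

# One SGD + momentum step with L2 weight decay on the weight matrices.
cnnUpdate <- function(params, grads, velocity, config) {
  lr <- config$learningRate; mom <- config$momentum
  wd <- config$weightDecay
  for (l in seq_along(params$W)) {
    velocity$W[[l]] <- mom * velocity$W[[l]] -
      lr * (grads$W[[l]] + wd * params$W[[l]])
    params$W[[l]] <- params$W[[l]] + velocity$W[[l]]
    velocity$b[[l]] <- mom * velocity$b[[l]] - lr * grads$b[[l]]
    params$b[[l]] <- params$b[[l]] + velocity$b[[l]]
    velocity$gamma[[l]] <- mom * velocity$gamma[[l]] - lr * grads$gamma[[l]]
    params$gamma[[l]] <- params$gamma[[l]] + velocity$gamma[[l]]
    velocity$beta[[l]] <- mom * velocity$beta[[l]] - lr * grads$beta[[l]]
    params$beta[[l]] <- params$beta[[l]] + velocity$beta[[l]]
  }
  velocity$Wd <- mom * velocity$Wd - lr * (grads$Wd + wd * params$Wd)
  params$Wd <- params$Wd + velocity$Wd
  velocity$bd <- mom * velocity$bd - lr * grads$bd
  params$bd <- params$bd + velocity$bd
  list(params = params, velocity = velocity)
}

cnnZeroVelocity <- function(params) {
  zeroLike <- function(x) {
    x[] <- 0
    x
  }
  v <- params
  for (l in seq_along(v$W)) {
    v$W[[l]] <- zeroLike(v$W[[l]]); v$b[[l]] <- zeroLike(v$b[[l]])
    v$gamma[[l]] <- zeroLike(v$gamma[[l]]); v$beta[[l]] <- zeroLike(v$beta[[l]])
  }
  v$Wd <- zeroLike(v$Wd); v$bd <- zeroLike(v$bd)
  v
}
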