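#' @include AllClasses.R annotation_io.R
NULL

# Summed-area table with a zero border: S[(r+1)+1, (c+1)+1] handles 0-based
# rectangle sums in O(1).
summedArea <- function(m) {
  s <- apply(m, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  rbind(0, cbind(0, s))
}

blockSums <- function(sat, rows0, cols0, size) {
  # rows0/cols0: 0-based anchor vectors; returns length(rows0) x length(cols0)
  r0 <- rows0 + 1L; r1 <- rows0 + size + 1L
  c0 <- cols0 + 1L; c1 <- cols0 + size + 1L
  sat[r1, c1, drop = FALSE] - sat[r0, c1, drop = FALSE] -
    sat[r1, c0, drop = FALSE] + sat[r0, c0, drop = FALSE]
}

emptyPatchMeta <- function() {
  data.frame(slideId = character(), row = integer(), col = integer(),
             label = integer(), factor = integer(),
             stringsAsFactors = FALSE)
}

newPatchSet <- function(tiles, meta, tileSize, splitTag = "unsplit") {
  new("PatchSet", tiles = tiles, meta = meta,
      tileSize = as.integer(tileSize), splitTag = splitTag)
}

#' Extract labeled tiles from annotated slide regions
#'
#' Walks a grid anchored at the slide origin with the given stride and emits
#' a tile with label L iff every pixel of its footprint lies inside the mask
#' of label L — the conservative reading of area-based annotation, where
#' marked regions are *surely* tumor or *surely* normal. With
#' `stride = tileSize` (the default) emitted footprints are pairwise
#' disjoint.
#'
#' @param slide a [SlideImage-class].
#' @param masks a [LabelMasks-class] with the same shape.
#' @param tileSize tile side in pixels (default 128).
#' @param stride grid stride in pixels (default `tileSize`).
#' @return a [PatchSet-class] (possibly empty when no tile fits).
#' @export
extractPatches <- function(slide, masks, tileSize = 128L,
                           stride = tileSize) {
  if (!is(slide, "SlideImage")) stop("slide must be a SlideImage")
  if (!is(masks, "LabelMasks")) stop("masks must be a LabelMasks")
  d <- dim(slide@pixels)
  if (!identical(dim(masks@tumorMask), d[1:2]))
    stop("masks shape must equal slide shape")
  tileSize <- asIntegerStrict(tileSize, "tileSize")
  stride <- asIntegerStrict(stride, "stride")
  h <- d[1]; w <- d[2]
  if (tileSize > h || tileSize > w)
    return(newPatchSet(array(0, c(tileSize, tileSize, 3L, 0L)),
                       emptyPatchMeta(), tileSize))
  rows0 <- seq.int(0L, h - tileSize, by = stride)
  cols0 <- seq.int(0L, w - tileSize, by = stride)
  full <- as.numeric(tileSize)^2
  satT <- summedArea(masks@tumorMask)
  satN <- summedArea(masks@normalMask)
  isT <- blockSums(satT, rows0, cols0, tileSize) == full
  isN <- blockSums(satN, rows0, cols0, tileSize) == full
  hits <- which(isT | isN, arr.ind = TRUE)
  n <- nrow(hits)
  tiles <- array(0, c(tileSize, tileSize, 3L, n))
  meta <- data.frame(slideId = rep(slide@slideId, n),
                     row = integer(n), col = integer(n),
                     label = integer(n),
                     factor = rep(slide@downsampleFactor, n),
                     stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    r0 <- rows0[hits[k, 1]]; c0 <- cols0[hits[k, 2]]
    tiles[, , , k] <- slide@pixels[r0 + seq_len(tileSize),
                                   c0 + seq_len(tileSize), , drop = FALSE]
    meta$row[k] <- r0; meta$col[k] <- c0
    meta$label[k] <- as.integer(isT[hits[k, 1], hits[k, 2]])
  }
  newPatchSet(tiles, meta, tileSize)
}

#' Combine several PatchSets into one
#'
#' @param sets list of [PatchSet-class] objects sharing one tile size.
#' @param splitTag tag for the combined set.
#' @return a [PatchSet-class].
#' @export
combinePatchSets <- function(sets, splitTag = "unsplit") {
  sets <- Filter(function(s) length(s) > 0L, sets)
  if (!length(sets))
    return(newPatchSet(array(0, c(128L, 128L, 3L, 0L)), emptyPatchMeta(),
                       128L, splitTag))
  ts <- unique(vapply(sets, function(s) s@tileSize, integer(1)))
  if (length(ts) != 1L) stop("all PatchSets must share one tile size")
  ns <- vapply(sets, length, integer(1))
  tiles <- array(0, c(ts, ts, 3L, sum(ns)))
  at <- 0L
  for (s in sets) {
    tiles[, , , at + seq_len(length(s))] <- s@tiles
    at <- at + length(s)
  }
  newPatchSet(tiles, do.call(rbind, lapply(sets, function(s) s@meta)),
              ts, splitTag)
}

#' Equalize tumor/normal patch counts by undersampling
#'
#' Uniformly subsamples the majority class without replacement down to the
#' minority count; deterministic given `seed`.
#'
#' @param dataset a [PatchSet-class] containing both classes.
#' @param seed integer RNG seed.
#' @return a balanced [PatchSet-class].
#' @export
balanceClasses <- function(dataset, seed) {
  if (!is(dataset, "PatchSet")) stop("dataset must be a PatchSet")
  lab <- dataset@meta$label
  idxT <- which(lab == 1); idxN <- which(lab == 0)
  if (!length(idxT)) stop("cannot balance: the tumor class is empty")
  if (!length(idxN)) stop("cannot balance: the normal class is empty")
  k <- min(length(idxT), length(idxN))
  keep <- withSeed(seed, {
    c(if (length(idxT) > k) sample(idxT, k) else idxT,
      if (length(idxN) > k) sample(idxN, k) else idxN)
  })
  dataset[sort(keep)]
}

#' Split slide identifiers into train/validation/test groups
#'
#' The split is by slide — all patches of one slide share a split — to avoid
#' leakage of slide-level appearance between sets. Group sizes honor the
#' fractions to the nearest integer; the test group takes the remainder.
#'
#' @param slideIds character vector of unique slide identifiers.
#' @param fractions numeric train/validation/test fractions summing to 1
#'   (default `c(0.70, 0.10, 0.20)`).
#' @param seed integer RNG seed; the assignment is a seeded permutation.
#' @return named list of character vectors `train`, `validation`, `test`.
#' @export
splitSlides <- function(slideIds, fractions = c(0.70, 0.10, 0.20), seed) {
  if (anyDuplicated(slideIds)) stop("slideIds must be unique")
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three numbers summing to 1")
  n <- length(slideIds)
  if (n < 1L) stop("need at least one slide")
  perm <- withSeed(seed, sample(slideIds))
  nTrain <- max(1L, min(n, round(fractions[1] * n)))
  nVal <- min(n - nTrain, round(fractions[2] * n))
  nTest <- n - nTrain - nVal
  if (nVal == 0L || nTest == 0L)
    warning("too few slides for a non-empty validation/test group")
  list(train = perm[seq_len(nTrain)],
       validation = perm[nTrain + seq_len(nVal)],
       test = perm[nTrain + nVal + seq_len(nTest)])
}

#' Persist / load a PatchSet as PNG tiles plus a CSV manifest
#'
#' Tiles are written as `tile_<i>.png` under `dir` together with
#' `manifest.csv` holding the provenance columns (`slideId`, `row`, `col`,
#' `label`, `factor`) and the split tag.
#'
#' @param dataset a [PatchSet-class].
#' @param dir output directory (created if needed).
#' @return `readPatchSet` returns the reconstructed [PatchSet-class].
#' @export
writePatchSet <- function(dataset, dir) {
  if (!is(dataset, "PatchSet")) stop("dataset must be a PatchSet")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mf <- dataset@meta
  mf$file <- sprintf("tile_%05d.png", seq_len(nrow(mf)))
  mf$splitTag <- dataset@splitTag
  mf$tileSize <- dataset@tileSize
  for (k in seq_len(length(dataset)))
    png::writePNG(dataset@tiles[, , , k] / 255, file.path(dir, mf$file[k]))
  utils::write.csv(mf, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname writePatchSet
#' @export
readPatchSet <- function(dir) {
  mf <- utils::read.csv(file.path(dir, "manifest.csv"),
                        stringsAsFactors = FALSE)
  ts <- if (nrow(mf)) mf$tileSize[1] else 128L
  tiles <- array(0, c(ts, ts, 3L, nrow(mf)))
  for (k in seq_len(nrow(mf)))
    tiles[, , , k] <- round(png::readPNG(file.path(dir, mf$file[k])) * 255)
  tag <- if (nrow(mf)) mf$splitTag[1] else "unsplit"
  newPatchSet(tiles, mf[, c("slideId", "row", "col", "label", "factor")],
              ts, tag)
}
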