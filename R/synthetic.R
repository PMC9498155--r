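#' @include AllClasses.R annotation_io.R utils.R
NULL

#' Construct a synthetic-slide specification
#'
#' Defaults describe the study conditions the generator emulates: a
#' bright-field H&E-like appearance with a pure white background, pink
#' cytoplasm fields and dark purple nuclei, where tumor regions are
#' hypercellular (higher nucleus density, larger nuclei) relative to normal
#' tissue. Regions are axis-aligned rectangles separated by more than one
#' tile side so no sliding window ever straddles two regions of different
#' classes.
#'
#' @param height,width canvas size in pixels (default 1024 x 1536, a
#'   desk-scale stand-in for gigapixel slides).
#' @param nTumorRegions,nNormalRegions regions per class (default 2 + 2).
#' @param regionSizeRange region side range in pixels.
#' @param tumorDensity,normalDensity expected nuclei per 1000 px^2.
#' @param tumorRadiusRange,normalRadiusRange nucleus radius ranges (px).
#' @param nucleusColor,cytoplasmColor,background RGB triples.
#' @param jitterSd sd of the additive Gaussian color jitter.
#' @param minSeparation minimum region gap in pixels.
#' @param maxPlacementTries region-size resampling budget per class.
#' @return a [SyntheticSlideSpec-class].
#' @export
syntheticSlideSpec <- function(height = 1024L, width = 1536L,
                               nTumorRegions = 2L, nNormalRegions = 2L,
                               regionSizeRange = c(288L, 384L),
                               tumorDensity = 7, normalDensity = 2,
                               tumorRadiusRange = c(3, 6),
                               normalRadiusRange = c(2, 4),
                               nucleusColor = c(70, 40, 120),
                               cytoplasmColor = c(232, 190, 210),
                               background = c(255, 255, 255),
                               jitterSd = 6,
                               minSeparation = 132L,
                               maxPlacementTries = 500L) {
  new("SyntheticSlideSpec",
      height = asIntegerStrict(height, "height"),
      width = asIntegerStrict(width, "width"),
      nTumorRegions = asIntegerStrict(nTumorRegions, "nTumorRegions"),
      nNormalRegions = asIntegerStrict(nNormalRegions, "nNormalRegions"),
      regionSizeRange = asIntegerStrict(regionSizeRange,
                                        "regionSizeRange"),
      tumorDensity = tumorDensity, normalDensity = normalDensity,
      tumorRadiusRange = tumorRadiusRange,
      normalRadiusRange = normalRadiusRange,
      nucleusColor = nucleusColor, cytoplasmColor = cytoplasmColor,
      background = background, jitterSd = jitterSd,
      minSeparation = asIntegerStrict(minSeparation, "minSeparation"),
      maxPlacementTries = asIntegerStrict(maxPlacementTries,
                                          "maxPlacementTries"))
}

rectsSeparated <- function(a, b, gap) {
  # a, b: c(r0, c0, r1, c1) inclusive; TRUE when the expanded boxes miss
  a[3] + gap < b[1] || b[3] + gap < a[1] ||
    a[4] + gap < b[2] || b[4] + gap < a[2]
}

# Minimum gaps: regions of different classes stay more than a window apart
# (so no sliding window mixes the two tissue classes); same-class regions
# only need to stay disjoint as annotations.
SAME_CLASS_GAP <- 16L

# Place n same-class regions inside a band: region sizes are resampled until
# they fit stacked along the band's long axis (bounded retries), then laid
# out in that axis with randomly jittered gaps and random offsets across it.
# Guarantees pairwise SAME_CLASS_GAP separation. Returns list of
# c(r0, c0, r1, c1), 0-based inclusive.
placeClassRegions <- function(band, n, sizeRange, tries, label) {
  if (n == 0L) return(list())
  bh <- band[2] - band[1] + 1L; bw <- band[4] - band[3] + 1L
  alongRows <- bh >= bw
  along <- if (alongRows) bh else bw
  across <- if (alongRows) bw else bh
  sizes <- NULL
  for (try in seq_len(tries)) {
    sA <- sample(sizeRange[1]:sizeRange[2], n, replace = TRUE)
    sX <- sample(sizeRange[1]:sizeRange[2], n, replace = TRUE)
    if (all(sX <= across) &&
        sum(sA) + (n - 1L) * SAME_CLASS_GAP <= along) {
      sizes <- list(sA = sA, sX = sX)
      break
    }
  }
  if (is.null(sizes))
    stop(sprintf(
      "could not place %d %s region(s) without overlap after %d tries",
      n, label, tries))
  slack <- along - sum(sizes$sA) - (n - 1L) * SAME_CLASS_GAP
  jitter <- sort(sample.int(slack + 1L, n, replace = TRUE) - 1L)
  startA <- jitter + cumsum(c(0L, utils::head(sizes$sA, -1L) +
                                SAME_CLASS_GAP))
  startX <- vapply(sizes$sX, function(s)
    sample.int(across - s + 1L, 1) - 1L, integer(1))
  lapply(seq_len(n), function(i) {
    if (alongRows) {
      r0 <- band[1] + startA[i]; c0 <- band[3] + startX[i]
      c(r0, c0, r0 + sizes$sA[i] - 1L, c0 + sizes$sX[i] - 1L)
    } else {
      r0 <- band[1] + startX[i]; c0 <- band[3] + startA[i]
      c(r0, c0, r0 + sizes$sX[i] - 1L, c0 + sizes$sA[i] - 1L)
    }
  })
}

drawRegion <- function(canvas, rect, density, radiusRange, spec) {
  r <- rect[1]:rect[3] + 1L
  c <- rect[2]:rect[4] + 1L
  hh <- length(r); ww <- length(c)
  for (ch in 1:3) canvas[r, c, ch] <- spec@cytoplasmColor[ch]
  nNuc <- stats::rpois(1, density * hh * ww / 1000)
  if (nNuc > 0) {
    cy <- stats::runif(nNuc, 1, hh)
    cx <- stats::runif(nNuc, 1, ww)
    rad <- stats::runif(nNuc, radiusRange[1], radiusRange[2])
    for (k in seq_len(nNuc)) {
      rr <- max(1, floor(cy[k] - rad[k])):min(hh, ceiling(cy[k] + rad[k]))
      cc <- max(1, floor(cx[k] - rad[k])):min(ww, ceiling(cx[k] + rad[k]))
      dy <- rr - cy[k]; dx <- cc - cx[k]
      disc <- outer(dy^2, dx^2, "+") <= rad[k]^2
      for (ch in 1:3) {
        block <- canvas[rect[1] + rr, rect[2] + cc, ch]
        block[disc] <- spec@nucleusColor[ch]
        canvas[rect[1] + rr, rect[2] + cc, ch] <- block
      }
    }
  }
  if (spec@jitterSd > 0) {
    noise <- stats::rnorm(hh * ww * 3L, sd = spec@jitterSd)
    dim(noise) <- c(hh, ww, 3L)
    canvas[r, c, ] <- clamp255(round(canvas[r, c, ] + noise))
  }
  canvas
}

#' Generate one synthetic annotated slide
#'
#' Deterministic given `seed`. The two classes are assigned separate bands
#' of the canvas (guaranteeing the cross-class separation), rectangles are
#' stacked inside each band with randomized sizes and offsets, textured
#' with nuclei and color jitter, and returned together with annotation
#' polygons that exactly bound the rendered regions (integer-corner
#' rectangles rasterize back to the same pixel footprint under the
#' pixel-center, boundary-inclusive rule).
#'
#' @param spec a [SyntheticSlideSpec-class].
#' @param seed integer RNG seed.
#' @param slideId identifier for the returned slide.
#' @return list with elements `slide` ([SlideImage-class]) and
#'   `annotations` ([AnnotationSet-class]).
#' @export
generateSlide <- function(spec, seed = 1L, slideId = "synthetic") {
  if (!is(spec, "SyntheticSlideSpec"))
    stop("spec must be a SyntheticSlideSpec")
  validObject(spec)
  withSeed(seed, {
    h <- spec@height; w <- spec@width
    labels <- c(rep("tumor", spec@nTumorRegions),
                rep("normal", spec@nNormalRegions))
    # The two classes live in separate bands of the canvas, so the
    # cross-class separation (no window may mix the classes) holds by
    # construction; a vertical or horizontal split is chosen among the
    # feasible orientations. Within a band only the small same-class gap is
    # enforced by rejection sampling.
    maxR <- min(spec@regionSizeRange[2], h - 2L, w - 2L)
    margin <- spec@minSeparation %/% 2L + 1L
    bands <- list(tumor = c(0L, h - 1L, 0L, w - 1L),
                  normal = c(0L, h - 1L, 0L, w - 1L))
    if (spec@nTumorRegions > 0L && spec@nNormalRegions > 0L) {
      canV <- w >= 2L * (maxR + margin)
      canH <- h >= 2L * (maxR + margin)
      if (!canV && !canH)
        stop("canvas too small to separate the two classes; enlarge it")
      vertical <- if (canV && canH) sample(c(TRUE, FALSE), 1) else canV
      extent <- if (vertical) w else h
      cut <- sample.int(extent - 2L * (maxR + margin) + 1L, 1) +
        maxR + margin - 1L
      first <- sample(c("tumor", "normal"), 1)
      second <- setdiff(TISSUE_LABELS, first)
      if (vertical) {
        bands[[first]] <- c(0L, h - 1L, 0L, cut - margin)
        bands[[second]] <- c(0L, h - 1L, cut + margin, w - 1L)
      } else {
        bands[[first]] <- c(0L, cut - margin, 0L, w - 1L)
        bands[[second]] <- c(cut + margin, h - 1L, 0L, w - 1L)
      }
    }
    rects <- c(
      placeClassRegions(bands$tumor, spec@nTumorRegions,
                        spec@regionSizeRange, spec@maxPlacementTries,
                        "tumor"),
      placeClassRegions(bands$normal, spec@nNormalRegions,
                        spec@regionSizeRange, spec@maxPlacementTries,
                        "normal"))
    canvas <- array(0, c(h, w, 3L))
    for (ch in 1:3) canvas[, , ch] <- spec@background[ch]
    polygons <- vector("list", length(labels))
    for (i in seq_along(labels)) {
      tumor <- labels[i] == "tumor"
      canvas <- drawRegion(canvas, rects[[i]],
                           if (tumor) spec@tumorDensity
                           else spec@normalDensity,
                           if (tumor) spec@tumorRadiusRange
                           else spec@normalRadiusRange,
                           spec)
      rc <- rects[[i]]
      polygons[[i]] <- matrix(c(rc[2], rc[1],
                                rc[4], rc[1],
                                rc[4], rc[3],
                                rc[2], rc[3]),
                              ncol = 2, byrow = TRUE)
    }
    list(slide = slideImage(canvas, slideId = slideId),
         annotations = annotationSet(polygons, labels))
  })
}

#' Generate a reproducible cohort of synthetic slides
#'
#' Per-slide seeds are derived deterministically from `masterSeed`, so the
#' cohort is reproducible as a whole while slides vary in layout and
#' jitter.
#'
#' @param nSlides number of slides.
#' @param spec a [SyntheticSlideSpec-class] shared by all slides.
#' @param masterSeed integer master seed.
#' @param idPrefix slide identifier prefix.
#' @return list of `list(slide=, annotations=)` entries, named by slide id.
#' @export
generateCohort <- function(nSlides, spec = syntheticSlideSpec(),
                           masterSeed = 1L, idPrefix = "synthetic") {
  seeds <- deriveSeeds(masterSeed, nSlides)
  out <- lapply(seq_len(nSlides), function(i)
    generateSlide(spec, seed = seeds[i],
                  slideId = sprintf("%s%02d", idPrefix, i)))
  names(out) <- vapply(out, function(x) slideId(x$slide), character(1))
  out
}
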