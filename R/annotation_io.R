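#' @include AllClasses.R utils.R
NULL

#' Construct a SlideImage
#'
#' @param pixels `H x W x 3` numeric array of 8-bit intensities, or an
#'   `H x W` matrix (replicated to three channels).
#' @param downsampleFactor integer >= 1 (1 = native resolution).
#' @param pixelSize micrometers per pixel, optional metadata.
#' @param slideId character identifier.
#' @return a [SlideImage-class].
#' @export
slideImage <- function(pixels, downsampleFactor = 1L, pixelSize = NA_real_,
                       slideId = "slide") {
  if (is.matrix(pixels))
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  new("SlideImage", pixels = pixels,
      downsampleFactor = asIntegerStrict(downsampleFactor,
                                         "downsampleFactor"),
      pixelSize = pixelSize, slideId = slideId)
}

#' Construct an AnnotationSet
#'
#' @param polygons list of regions; each region either an `n x 2` matrix of
#'   `(x, y)` vertices (single outer ring) or a list of such matrices (outer
#'   ring first, holes after).
#' @param labels character vector of `"tumor"`/`"normal"` (case-insensitive),
#'   one per region.
#' @return an [AnnotationSet-class].
#' @export
annotationSet <- function(polygons = list(), labels = character()) {
  polygons <- lapply(polygons, function(p) {
    if (is.matrix(p)) list(p) else lapply(p, as.matrix)
  })
  new("AnnotationSet", polygons = polygons, labels = tolower(labels))
}

#' Mask the white slide background
#'
#' A pixel counts as background when all three channels are at least
#' `whitenessThreshold` (i.e. `min(R, G, B) >= whitenessThreshold`), the
#' near-white appearance of glass outside the tissue section. The returned
#' mask marks tissue (non-background).
#'
#' @param slide a [SlideImage-class].
#' @param whitenessThreshold intensity in `[0, 255]`; default 220.
#' @return logical `H x W` matrix, `TRUE` = tissue.
#' @export
maskBackground <- function(slide, whitenessThreshold = 220) {
  if (!is(slide, "SlideImage")) stop("slide must be a SlideImage")
  px <- slide@pixels
  if (length(dim(px)) != 3L || dim(px)[3] != 3L)
    stop("slide raster must be RGB (H x W x 3)")
  stopifnotScalar(whitenessThreshold, "whitenessThreshold")
  minc <- pmin(px[, , 1], px[, , 2], px[, , 3])
  minc < whitenessThreshold
}

#' Downsample a slide by integer block averaging
#'
#' Output dimensions are `ceiling(input / factor)`; each output pixel is the
#' mean of its (possibly partial, at the right/bottom edge) `factor x factor`
#' source block, rounded to the nearest integer (ties to even). The slide's
#' `downsampleFactor` is multiplied by `factor` and `pixelSize` scaled
#' accordingly.
#'
#' @param slide a [SlideImage-class].
#' @param factor positive integer; 1 returns the input unchanged.
#' @return a [SlideImage-class].
#' @export
downsampleSlide <- function(slide, factor) {
  if (!is(slide, "SlideImage")) stop("slide must be a SlideImage")
  factor <- asIntegerStrict(factor, "factor")
  if (length(factor) != 1L || factor < 1L)
    stop("factor must be a single integer >= 1")
  if (factor == 1L) return(slide)
  px <- slide@pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  oh <- ceiling(h / factor); ow <- ceiling(w / factor)
  rowg <- (seq_len(h) - 1L) %/% factor + 1L   # block row of each source row
  colg <- (seq_len(w) - 1L) %/% factor + 1L
  out <- array(0, dim = c(oh, ow, 3L))
  for (ch in 1:3) {
    # sum rows into row-blocks, then columns into column-blocks
    s <- rowsum(px[, , ch], rowg)                 # oh x w
    s <- t(rowsum(t(s), colg))                    # oh x ow
    cnt <- tabulate(rowg, oh) %o% tabulate(colg, ow)
    out[, , ch] <- round(s / cnt)
  }
  new("SlideImage", pixels = out,
      downsampleFactor = slide@downsampleFactor * factor,
      pixelSize = slide@pixelSize * factor,
      slideId = slide@slideId)
}

# Even-odd point-in-polygon for a vector of points against one region
# (list of rings; ring 1 outer, others holes). Points on any ring edge are
# counted inside. Coordinates are (x, y); pixel centers sit at integers.
pointsInRegion <- function(px, py, rings, eps = 1e-9) {
  crossings <- integer(length(px))
  onEdge <- logical(length(px))
  for (ring in rings) {
    v <- ring
    n <- nrow(v)
    if (n >= 2L && all(abs(v[1, ] - v[n, ]) < eps)) {
      v <- v[-n, , drop = FALSE]   # drop GeoJSON closing vertex
      n <- n - 1L
    }
    if (n < 3L) next
    x1 <- v[, 1]; y1 <- v[, 2]
    x2 <- v[c(2:n, 1L), 1]; y2 <- v[c(2:n, 1L), 2]
    for (e in seq_len(n)) {
      a1 <- x1[e]; b1 <- y1[e]; a2 <- x2[e]; b2 <- y2[e]
      straddles <- (b1 > py) != (b2 > py)
      if (any(straddles)) {
        xi <- a1 + (a2 - a1) * (py - b1) / (b2 - b1)
        crossings <- crossings + (straddles & (px < xi - eps))
      }
      # boundary test: zero cross product and within the edge bounding box
      cr <- (a2 - a1) * (py - b1) - (b2 - b1) * (px - a1)
      seg <- abs(cr) <= eps * (1 + abs(a2 - a1) + abs(b2 - b1)) &
        px >= pmin(a1, a2) - eps & px <= pmax(a1, a2) + eps &
        py >= pmin(b1, b2) - eps & py <= pmax(b1, b2) + eps
      onEdge <- onEdge | seg
    }
  }
  (crossings %% 2L == 1L) | onEdge
}

# Rasterize one region into a full H x W logical matrix (0-based pixel
# coordinates: pixel (r, c) center at x = c, y = r).
rasterizeRegion <- function(rings, h, w) {
  out <- matrix(FALSE, h, w)
  xs <- unlist(lapply(rings, function(r) r[, 1]))
  ys <- unlist(lapply(rings, function(r) r[, 2]))
  r0 <- max(0L, floor(min(ys))); r1 <- min(h - 1L, ceiling(max(ys)))
  c0 <- max(0L, floor(min(xs))); c1 <- min(w - 1L, ceiling(max(xs)))
  if (r0 > r1 || c0 > c1) return(out)
  rows <- r0:r1; cols <- c0:c1
  py <- rep(rows, times = length(cols))
  px <- rep(cols, each = length(rows))
  inside <- pointsInRegion(px, py, rings)
  out[cbind(py + 1L, px + 1L)] <- inside   # 0-based (row, col) -> 1-based
  out
}

#' Rasterize labeled annotations into per-class masks
#'
#' A pixel belongs to a class mask iff its center lies inside (or on the
#' boundary of) a polygon of that class under the even-odd rule; interior
#' rings are holes. Annotations are stored at native resolution; when
#' rasterizing against a downsampled slide, pass its `factor` and the
#' coordinates are scaled by `1/factor` first.
#'
#' @param annotations an [AnnotationSet-class].
#' @param shape integer `c(H, W)` of the target raster.
#' @param tissue optional logical `H x W` tissue mask (from
#'   [maskBackground()]); defaults to all-tissue.
#' @param factor downsample factor of the target raster relative to the
#'   annotation coordinates (default 1).
#' @return a [LabelMasks-class].
#' @export
rasterizeAnnotations <- function(annotations, shape, tissue = NULL,
                                 factor = 1L) {
  if (!is(annotations, "AnnotationSet"))
    stop("annotations must be an AnnotationSet")
  h <- shape[1]; w <- shape[2]
  if (is.null(tissue)) tissue <- matrix(TRUE, h, w)
  masks <- list(tumor = matrix(FALSE, h, w),
                normal = matrix(FALSE, h, w))
  regionMasks <- vector("list", length(annotations@labels))
  for (i in seq_along(annotations@labels)) {
    rings <- lapply(annotations@polygons[[i]], function(r) r / factor)
    m <- rasterizeRegion(rings, h, w)
    regionMasks[[i]] <- m
    lab <- annotations@labels[i]
    masks[[lab]] <- masks[[lab]] | m
  }
  overlap <- masks$tumor & masks$normal
  if (any(overlap)) {
    labs <- annotations@labels
    bad <- character()
    for (i in seq_along(labs)) for (j in seq_along(labs)) {
      if (i < j && labs[i] != labs[j] &&
          any(regionMasks[[i]] & regionMasks[[j]]))
        bad <- c(bad, sprintf("(%d, %d)", i, j))
    }
    stop("tumor/normal annotations overlap; offending region pairs: ",
         paste(bad, collapse = ", "))
  }
  new("LabelMasks",
      tumorMask = masks$tumor, normalMask = masks$normal,
      annotatedMask = masks$tumor | masks$normal,
      tissueMask = tissue)
}

normalizeLabel <- function(x) {
  lx <- tolower(x)
  if (!lx %in% TISSUE_LABELS)
    stop(sprintf("unknown annotation class '%s' (expected Tumor or Normal)",
                 x))
  lx
}

#' Read annotations from a GeoJSON FeatureCollection
#'
#' Expects the QuPath export dialect: each `Feature` carries a `Polygon` (or
#' `MultiPolygon`, split into one region per polygon) geometry and a
#' `properties.classification.name` of `Tumor` or `Normal`
#' (case-insensitive). Coordinates are `(x, y)` slide pixels.
#'
#' @param path GeoJSON file path.
#' @return an [AnnotationSet-class].
#' @export
readAnnotations <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(doc$type, "FeatureCollection")) doc$features
           else list(doc)
  polygons <- list(); labels <- character()
  ringToMatrix <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    # GeoJSON rings repeat the first vertex; store the open form
    if (nrow(m) > 3L && all(m[1, ] == m[nrow(m), ]))
      m <- m[-nrow(m), , drop = FALSE]
    m
  }
  for (f in feats) {
    cls <- f$properties$classification$name
    if (is.null(cls)) cls <- f$properties$classification  # tolerant variant
    if (is.null(cls) || !is.character(cls))
      stop("feature without a classification name property")
    lab <- normalizeLabel(cls)
    g <- f$geometry
    polys <- switch(g$type,
      Polygon = list(g$coordinates),
      MultiPolygon = g$coordinates,
      stop(sprintf("unsupported geometry type '%s'", g$type)))
    for (p in polys) {
      polygons[[length(polygons) + 1L]] <- lapply(p, ringToMatrix)
      labels <- c(labels, lab)
    }
  }
  annotationSet(polygons, labels)
}

#' Write annotations as a GeoJSON FeatureCollection
#'
#' Inverse of [readAnnotations()]: round-trips vertices and labels exactly.
#' Rings are closed on output (first vertex repeated) as GeoJSON requires.
#'
#' @param annotations an [AnnotationSet-class].
#' @param path output file path.
#' @export
writeAnnotations <- function(annotations, path) {
  if (!is(annotations, "AnnotationSet"))
    stop("annotations must be an AnnotationSet")
  closeRing <- function(m) {
    if (nrow(m) < 1L || !all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ])
    lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
  }
  feats <- lapply(seq_along(annotations@labels), function(i) {
    lab <- annotations@labels[i]
    list(
      type = "Feature",
      geometry = list(
        type = "Polygon",
        coordinates = lapply(annotations@polygons[[i]], closeRing)
      ),
      properties = list(classification = list(
        name = c(tumor = "Tumor", normal = "Normal")[[lab]]))
    )
  })
  doc <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read a slide raster from PNG or TIFF
#'
#' @param path image path (`.png`, `.tif`, `.tiff`).
#' @param downsampleFactor,pixelSize,slideId metadata for the returned
#'   object; `slideId` defaults to the file stem.
#' @return a [SlideImage-class].
#' @export
readSlide <- function(path, downsampleFactor = 1L, pixelSize = NA_real_,
                      slideId = NULL) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported raster format '.%s'", ext)))
  if (is.matrix(raw)) raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]  # drop alpha
  if (is.null(slideId))
    slideId <- tools::file_path_sans_ext(basename(path))
  slideImage(round(raw * 255), downsampleFactor = downsampleFactor,
             pixelSize = pixelSize, slideId = slideId)
}

#' Write a slide raster to PNG or TIFF
#'
#' @param slide a [SlideImage-class].
#' @param path output path (`.png`, `.tif`, `.tiff`).
#' @export
writeSlide <- function(slide, path) {
  if (!is(slide, "SlideImage")) stop("slide must be a SlideImage")
  img <- slide@pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L,
                           compression = "LZW"),
    stop(sprintf("unsupported raster format '.%s'", ext)))
  invisible(path)
}

#' Read / write a binary mask as PNG
#'
#' Masks are stored as 8-bit grayscale PNG with 0 = false and 255 = true.
#'
#' @param mask logical matrix.
#' @param path PNG path.
#' @return `readMask` returns a logical matrix.
#' @export
writeMask <- function(mask, path) {
  png::writePNG(ifelse(mask, 1, 0), path)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}
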