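#' Kernel-based object segmentation
#'
#' Detects bright compact regions at the kernel scale. The local foreground
#' estimate is a box mean of width `kernelSize`; the local background is a
#' median filter of radius three times the kernel width, wide enough that
#' objects at the kernel scale cannot dominate the window. The decision score is the
#' offset-aware local contrast ratio
#' \deqn{score = (mean_k - floor) / max(median_{3k} - floor, 1)}
#' with `floor` the global plane minimum, and a pixel enters the mask when
#' the score reaches the sensitivity-derived ratio
#' \deqn{r(s) = 1 + (100 - s) / 50}
#' so sensitivity 50 demands a local brightness-to-background ratio of 2,
#' and higher sensitivity demands less contrast. Subtracting the global
#' floor makes the criterion exactly invariant to a constant intensity
#' offset while preserving the ratio reading of sensitivity.
#'
#' @param plane 2D numeric matrix of non-negative finite intensities.
#' @param params an [ObjectSegParams-class] (kernel width, sensitivity).
#' @return a binary mask (logical matrix).
#' @examples
#' pl <- matrix(100, 64, 64)
#' pl[20:30, 20:30] <- 2000
#' sum(segmentObjects(pl, objectSegParams(15, 50)))
#' @export
segmentObjects <- function(plane, params = objectSegParams()) {
  stopifnot(is(params, "ObjectSegParams"))
  if (!is.matrix(plane) || anyNA(plane) || any(!is.finite(plane)) || any(plane < 0))
    stop("plane must be a finite non-negative matrix", call. = FALSE)
  k <- params@kernelSize
  if (k > min(dim(plane)))
    stop(sprintf("kernelSize %d exceeds image dimensions %d x %d",
                 k, nrow(plane), ncol(plane)), call. = FALSE)
  floorv <- min(plane)
  fg <- .meanFilter(plane, k) - floorv
  bg <- .medianFilter16(plane, min(3L * as.integer(k), (min(dim(plane)) - 1L) %/% 2L)) - floorv
  ratio <- fg / pmax(bg, 1)
  r <- 1 + (100 - params@sensitivity) / 50
  mask <- ratio >= r
  dim(mask) <- dim(plane)
  mask
}

#' Seed-guided nuclear segmentation
#'
#' Grows one candidate nucleus per seed object. Growth is nearest-seed
#' assignment (exact Euclidean distance to the seed region) restricted to
#' the region where the lightly smoothed plane stays above the background
#' threshold
#' \deqn{bg \cdot (1 + (100 - s) / 100)}
#' with `bg` the plane median (at least 1). Each candidate keeps only the
#' connected part that contains its seed, is smoothed by one opening with a
#' disc of radius 2 (the rounded-object constraint), and is discarded when
#' its area falls below `minTargetArea`. Surviving nuclei are relabelled
#' 1..N in raster order; outputs are pairwise disjoint and each contains at
#' least one pixel of its seed.
#'
#' @param plane 2D intensity matrix (the nuclear stain).
#' @param seeds integer label map of seed objects (from [segmentObjects()]
#'   plus post-processing); empty seeds give an empty label map.
#' @param params a [NuclearSegParams-class].
#' @param smooth odd width of the box pre-smoothing filter; 1 disables.
#' @return an integer label map of nuclei.
#' @export
segmentNuclei <- function(plane, seeds, params = nuclearSegParams(), smooth = 3) {
  stopifnot(is(params, "NuclearSegParams"))
  .assertLabelMap(seeds, "seeds")
  if (!identical(dim(plane), dim(seeds)))
    stop("seeds not aligned to plane shape", call. = FALSE)
  out <- matrix(0L, nrow(plane), ncol(plane))
  if (max(seeds) == 0L) return(out)
  sm <- if (smooth > 1) .meanFilter(plane, smooth) else plane
  bg <- max(stats::median(plane), 1)
  grow <- sm >= bg * (1 + (100 - params@sensitivity) / 100)
  dim(grow) <- dim(plane)
  assign <- .nearestSeedAssign(grow, seeds)
  open_kern <- .seFootprint(structuringElement("disc", 5))
  keep <- list()
  for (k in sort(unique(assign[assign > 0L]))) {
    mk <- assign == k
    if (!any(mk)) next
    bb <- .bbox(mk, pad = 3L)
    sub <- mk[bb[1L]:bb[2L], bb[3L]:bb[4L], drop = FALSE]
    seedSub <- (seeds == k)[bb[1L]:bb[2L], bb[3L]:bb[4L], drop = FALSE]
    ## keep only the connected part holding the seed
    cc <- .labelCC(sub, 8L)
    own <- unique(cc[seedSub & sub])
    own <- own[own > 0L]
    if (!length(own)) next
    sub <- cc %in% own
    dim(sub) <- dim(cc)
    ## rounded-object constraint: one opening, disc radius 2
    sub <- .binDilate(.binErode(sub, open_kern), open_kern)
    if (sum(sub) < params@minTargetArea) next
    if (!any(sub & seedSub)) next
    full <- matrix(FALSE, nrow(plane), ncol(plane))
    full[bb[1L]:bb[2L], bb[3L]:bb[4L]] <- sub
    keep[[length(keep) + 1L]] <- full
  }
  lab <- 0L
  for (full in keep) {
    lab <- lab + 1L
    out[full] <- lab
  }
  .relabelRaster(out)
}

#' Intensity-range segmentation
#'
#' Marks every pixel whose value lies inside the inclusive range; no size
#' filtering is applied (any object size is allowed).
#'
#' @param plane 2D intensity matrix.
#' @param range an [IntensityRange-class]; both bounds inclusive.
#' @return a binary mask.
#' @examples
#' segmentIntensity(matrix(c(0, 1, 65535), 1, 3), intensityRange(1, 65535))
#' @export
segmentIntensity <- function(plane, range = intensityRange()) {
  stopifnot(is(range, "IntensityRange"), is.matrix(plane))
  mask <- plane >= range@minimum & plane <= range@maximum
  dim(mask) <- dim(plane)
  mask
}

#' Connected-component labelling
#'
#' Labels maximal connected regions 1..N, ordered by each component's first
#' pixel in row-major raster order (top-left first).
#'
#' @param mask binary mask.
#' @param connectivity 4 or 8 (default 8: diagonal contact joins objects).
#' @return an integer label map.
#' @examples
#' m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
#' max(labelComponents(m, 4)); max(labelComponents(m, 8))
#' @export
labelComponents <- function(mask, connectivity = 8L) {
  .assertMask(mask)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8", call. = FALSE)
  .labelCC(mask, connectivity)
}

#' Automatic intensity range by Otsu thresholding
#'
#' Computes the Otsu threshold t of the integer histogram and returns the
#' inclusive range (t+1, 65535). Used by the protocol engine when an
#' intensity-segmentation step declares `range: auto`.
#'
#' @param plane 2D integer intensity matrix.
#' @return an [IntensityRange-class].
#' @export
autoIntensityRange <- function(plane) {
  t <- .otsuThreshold(plane)
  intensityRange(min(t + 1, 65535), 65535)
}
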