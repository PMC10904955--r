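#' Binary erosion
#'
#' Standard morphological erosion with a centred structuring element;
#' pixels outside the image count as background, so the output is always a
#' subset of the input. Smooths object boundaries.
#'
#' @param mask binary mask.
#' @param se a [StructuringElement-class]; the default disc follows the
#'   protocol reading of "kernel size" as the disc diameter.
#' @return a binary mask.
#' @examples
#' m <- matrix(FALSE, 7, 7); m[2:6, 2:6] <- TRUE
#' sum(erodeMask(m, structuringElement("square", 3)))  # 3x3 core
#' @export
erodeMask <- function(mask, se = structuringElement("disc", 3)) {
  .assertMask(mask)
  stopifnot(is(se, "StructuringElement"))
  .binErode(mask, .seFootprint(se))
}

#' Hole filling
#'
#' Background components not connected to the image border (4-connectivity,
#' the dual of the 8-connected foreground) are turned into foreground.
#' Extensive and idempotent; bays that reach the border are untouched.
#'
#' @param mask binary mask.
#' @return a binary mask containing the input.
#' @export
fillHoles <- function(mask) {
  .assertMask(mask)
  if (!any(!mask)) return(mask)
  bg <- .labelCC(!mask, 4L)
  borderLabs <- unique(c(bg[1L, ], bg[nrow(bg), ], bg[, 1L], bg[, ncol(bg)]))
  borderLabs <- borderLabs[borderLabs > 0L]
  hole <- bg > 0L & !(bg %in% borderLabs)
  dim(hole) <- dim(mask)
  mask | hole
}

#' Per-object hole filling on a label map
#'
#' Fills each labelled object's enclosed holes with that object's label.
#' Holes are enclosed by a single object, so assignments are unambiguous;
#' pixels of other labels are never altered.
#'
#' @param labels integer label map.
#' @return an integer label map.
#' @export
fillHolesLabels <- function(labels) {
  .assertLabelMap(labels)
  storage.mode(labels) <- "integer"
  n <- max(labels)
  if (n == 0L) return(labels)
  for (k in seq_len(n)) {
    mk <- labels == k
    if (!any(mk)) next
    bb <- .bbox(mk, pad = 1L)
    sub <- mk[bb[1L]:bb[2L], bb[3L]:bb[4L], drop = FALSE]
    filled <- fillHoles(sub)
    added <- filled & !sub
    if (any(added)) {
      block <- labels[bb[1L]:bb[2L], bb[3L]:bb[4L], drop = FALSE]
      block[added & block == 0L] <- k
      labels[bb[1L]:bb[2L], bb[3L]:bb[4L]] <- block
    }
  }
  labels
}

#' Area sieve
#'
#' Retains objects whose pixel area satisfies the predicate (strict
#' inequality; an object exactly at the threshold is removed). Survivors
#' are relabelled 1..M preserving their original order; surviving objects'
#' pixel sets are unchanged.
#'
#' @param labels integer label map.
#' @param pred a [SievePredicate-class].
#' @return an integer label map of the surviving objects.
#' @export
sieveObjects <- function(labels, pred) {
  .assertLabelMap(labels)
  stopifnot(is(pred, "SievePredicate"))
  storage.mode(labels) <- "integer"
  n <- max(labels)
  if (n == 0L) return(labels)
  areas <- .labelAreas(labels)
  keep <- if (pred@mode == "greater_than") areas > pred@areaThreshold
          else areas < pred@areaThreshold
  map <- integer(n)
  map[keep] <- seq_len(sum(keep))
  sel <- labels > 0L
  labels[sel] <- map[labels[sel]]
  labels
}

#' Nuclei-seeded clump breaking
#'
#' Splits merged foreground regions using a second target (typically
#' nuclei) as separators: every mask pixel in a component that contains
#' second-target pixels is assigned the label of its nearest second-target
#' object (exact Euclidean distance; segmentation boundaries fall at equal
#' distances between targets, i.e. the generalised Voronoi partition
#' restricted to the mask). Components containing no second-target object
#' keep a single fresh label. No pixel is created or deleted.
#'
#' Distance is measured to the nearest pixel of the seed region by default,
#' or to seed centroids with `distanceTo = "centroid"`; distance ties go to
#' the lower seed label.
#'
#' @param mask binary mask to split.
#' @param secondTarget integer label map of separator objects.
#' @param distanceTo `"region"` (default) or `"centroid"`.
#' @param connectivity component connectivity for the seedless-component
#'   rule (default 8).
#' @return an integer label map; seed-derived objects first (in ascending
#'   seed order), then seedless components in raster order.
#' @export
breakClumps <- function(mask, secondTarget, distanceTo = c("region", "centroid"),
                        connectivity = 8L) {
  .assertMask(mask)
  .assertLabelMap(secondTarget, "secondTarget")
  distanceTo <- match.arg(distanceTo)
  if (!identical(dim(mask), dim(secondTarget)))
    stop("mask and secondTarget must share dimensions", call. = FALSE)
  storage.mode(secondTarget) <- "integer"
  comp <- .labelCC(mask, as.integer(connectivity))
  nComp <- max(comp)
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (nComp == 0L) return(out)
  ## components holding at least one second-target pixel get Voronoi labels
  seeded <- sort(unique(comp[comp > 0L & secondTarget > 0L]))
  seededMask <- comp > 0L & (comp %in% seeded)
  dim(seededMask) <- dim(mask)
  if (any(seededMask)) {
    vor <- .nearestSeedAssign(seededMask, secondTarget, distanceTo)
    labs <- sort(unique(vor[vor > 0L]))
    map <- integer(max(labs))
    map[labs] <- seq_along(labs)
    sel <- vor > 0L
    out[sel] <- map[vor[sel]]
  }
  nextLab <- max(out)
  loose <- setdiff(seq_len(nComp), seeded)
  for (k in loose) {  # comp labels already in raster order
    nextLab <- nextLab + 1L
    out[comp == k] <- nextLab
  }
  out
}
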