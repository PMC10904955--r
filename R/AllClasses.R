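## S4 classes for the chipcyte pipeline. Binary masks and label maps are
## deliberately plain matrices (logical / integer) rather than S4 wrappers:
## they flow through EBImage kernels and tight loops, and the validity
## predicates below are applied at operation boundaries instead.

.CHANNEL_ROLES <- c("nuclear", "pan_cell", "gfp", "rfp")

#' Test whether an object is a binary mask
#'
#' A binary mask is a 2D logical matrix with no missing values.
#'
#' @param x object to test.
#' @return `TRUE` or `FALSE`.
#' @export
isBinaryMask <- function(x) {
  is.matrix(x) && is.logical(x) && !anyNA(x)
}

#' Test whether an object is a label map
#'
#' A label map is a 2D integer (or integer-valued numeric) matrix with
#' non-negative entries; 0 is background and labels 1..N are all present
#' (contiguous labelling).
#'
#' @param x object to test.
#' @return `TRUE` or `FALSE`.
#' @export
isLabelMap <- function(x) {
  if (!is.matrix(x) || anyNA(x) || !is.numeric(x)) return(FALSE)
  v <- as.vector(x)
  if (any(v < 0) || any(v != floor(v))) return(FALSE)
  n <- max(v)
  n == 0 || all(seq_len(n) %in% v)
}

.assertMask <- function(x, what = "mask") {
  if (!isBinaryMask(x)) stop(what, " must be a 2D logical matrix without NAs", call. = FALSE)
  invisible(x)
}

.assertLabelMap <- function(x, what = "labels") {
  if (!is.matrix(x) || anyNA(x) || !is.numeric(x) || any(x < 0) || any(x != floor(x)))
    stop(what, " must be a 2D matrix of non-negative integers", call. = FALSE)
  invisible(x)
}

## ---------------------------------------------------------------------------
## MultiChannelImage
## ---------------------------------------------------------------------------

#' Multi-channel fluorescence field
#'
#' One field of view: aligned per-channel intensity planes keyed by channel
#' role (`nuclear`, `pan_cell`, `gfp`, `rfp`). Intensities are integer photon
#' counts in 0..65535 (8-bit inputs are carried unscaled within that range).
#'
#' @slot planes named list of integer matrices, one per channel role; all
#'   planes share identical dimensions.
#' @slot pixelSize physical pixel size in microns/pixel, or `NA` when
#'   uncalibrated (physical-unit areas are then omitted from measurements).
#' @export
setClass("MultiChannelImage",
  representation(planes = "list", pixelSize = "numeric"),
  prototype(planes = list(), pixelSize = NA_real_))

setValidity("MultiChannelImage", function(object) {
  p <- object@planes
  if (length(p) == 0L) return("at least one channel plane is required")
  if (is.null(names(p)) || any(!nzchar(names(p)))) return("planes must be named by channel role")
  if (anyDuplicated(names(p))) return("each channel role may appear at most once")
  if (!all(names(p) %in% .CHANNEL_ROLES))
    return(paste0("unknown channel role(s): ",
                  paste(setdiff(names(p), .CHANNEL_ROLES), collapse = ", ")))
  d <- dim(p[[1L]])
  for (nm in names(p)) {
    m <- p[[nm]]
    if (!is.matrix(m) || !is.numeric(m)) return(paste0("plane '", nm, "' is not a numeric matrix"))
    if (!identical(dim(m), d)) return("all planes must share identical dimensions")
    if (anyNA(m) || any(m < 0) || any(m > 65535) || any(m != floor(m)))
      return(paste0("plane '", nm, "' must hold integer intensities in 0..65535"))
  }
  if (length(object@pixelSize) != 1L) return("pixelSize must be a single value")
  if (!is.na(object@pixelSize) && object@pixelSize <= 0) return("pixelSize must be positive")
  TRUE
})

#' Construct a MultiChannelImage
#'
#' @param planes named list of integer intensity matrices (names are channel
#'   roles among `nuclear`, `pan_cell`, `gfp`, `rfp`); identical dimensions.
#' @param pixelSize optional microns per pixel.
#' @return a [MultiChannelImage-class] object.
#' @examples
#' img <- MultiChannelImage(list(nuclear = matrix(0L, 8, 8)))
#' dim(img)
#' @export
MultiChannelImage <- function(planes, pixelSize = NA_real_) {
  planes <- lapply(planes, function(m) { storage.mode(m) <- "integer"; m })
  new("MultiChannelImage", planes = planes, pixelSize = as.numeric(pixelSize))
}

#' @describeIn MultiChannelImage field dimensions (rows, columns).
#' @param x a `MultiChannelImage`.
#' @export
setMethod("dim", "MultiChannelImage", function(x) dim(x@planes[[1L]]))

setMethod("show", "MultiChannelImage", function(object) {
  d <- dim(object)
  cat(sprintf("MultiChannelImage: %d x %d px, channels [%s]%s\n",
              d[1L], d[2L], paste(names(object@planes), collapse = ", "),
              if (is.na(object@pixelSize)) "" else
                sprintf(", %.3g um/px", object@pixelSize)))
})

## ---------------------------------------------------------------------------
## Segmentation / post-processing parameter classes
## ---------------------------------------------------------------------------

#' Kernel-based object segmentation parameters
#'
#' @slot kernelSize odd kernel width in pixels (>= 3).
#' @slot sensitivity score in (0, 100]; higher sensitivity demands less local
#'   contrast (see [segmentObjects()]).
#' @export
setClass("ObjectSegParams", representation(kernelSize = "numeric", sensitivity = "numeric"))

setValidity("ObjectSegParams", function(object) {
  k <- object@kernelSize; s <- object@sensitivity
  if (length(k) != 1L || is.na(k) || k < 3 || k != floor(k) || k %% 2 == 0)
    return("kernelSize must be an odd integer >= 3")
  if (length(s) != 1L || is.na(s) || s <= 0 || s > 100)
    return("sensitivity must lie in (0, 100]")
  TRUE
})

#' @rdname ObjectSegParams-class
#' @param kernelSize odd kernel width in pixels.
#' @param sensitivity sensitivity score in (0, 100].
#' @return an `ObjectSegParams` object.
#' @export
objectSegParams <- function(kernelSize = 15, sensitivity = 50)
  new("ObjectSegParams", kernelSize = as.numeric(kernelSize),
      sensitivity = as.numeric(sensitivity))

#' Seed-guided nuclear segmentation parameters
#'
#' @slot minTargetArea minimum nucleus area in pixels^2; smaller candidates
#'   are discarded.
#' @slot sensitivity score in (0, 100]; controls how far growth extends above
#'   the background level (see [segmentNuclei()]).
#' @export
setClass("NuclearSegParams", representation(minTargetArea = "numeric", sensitivity = "numeric"))

setValidity("NuclearSegParams", function(object) {
  if (length(object@minTargetArea) != 1L || is.na(object@minTargetArea) ||
      object@minTargetArea <= 0)
    return("minTargetArea must be a positive number of pixels")
  s <- object@sensitivity
  if (length(s) != 1L || is.na(s) || s <= 0 || s > 100)
    return("sensitivity must lie in (0, 100]")
  TRUE
})

#' @rdname NuclearSegParams-class
#' @param minTargetArea minimum nucleus area (pixels^2).
#' @param sensitivity sensitivity score in (0, 100].
#' @return a `NuclearSegParams` object.
#' @export
nuclearSegParams <- function(minTargetArea = 600, sensitivity = 15)
  new("NuclearSegParams", minTargetArea = as.numeric(minTargetArea),
      sensitivity = as.numeric(sensitivity))

#' Inclusive intensity range for intensity segmentation
#'
#' @slot minimum lower bound (counts), inclusive.
#' @slot maximum upper bound (counts), inclusive.
#' @export
setClass("IntensityRange", representation(minimum = "numeric", maximum = "numeric"))

setValidity("IntensityRange", function(object) {
  lo <- object@minimum; hi <- object@maximum
  if (length(lo) != 1L || length(hi) != 1L || is.na(lo) || is.na(hi))
    return("minimum and maximum must be single values")
  if (lo < 0 || hi > 65535 || lo > hi)
    return("must satisfy 0 <= minimum <= maximum <= 65535")
  TRUE
})

#' @rdname IntensityRange-class
#' @param minimum inclusive lower bound.
#' @param maximum inclusive upper bound.
#' @return an `IntensityRange` object.
#' @export
intensityRange <- function(minimum = 1, maximum = 65535)
  new("IntensityRange", minimum = as.numeric(minimum), maximum = as.numeric(maximum))

#' Structuring element for binary morphology
#'
#' `size` is the kernel width in pixels. Kernels are centred; an even width
#' is realised as the symmetric footprint of radius `size/2` (so a disc of
#' width 16 is the exact Euclidean disc of radius 8).
#'
#' @slot shape `"disc"` or `"square"`.
#' @slot size kernel width in pixels (>= 1).
#' @export
setClass("StructuringElement", representation(shape = "character", size = "numeric"))

setValidity("StructuringElement", function(object) {
  if (!object@shape %in% c("disc", "square")) return("shape must be 'disc' or 'square'")
  if (length(object@size) != 1L || is.na(object@size) || object@size < 1 ||
      object@size != floor(object@size))
    return("size must be an integer >= 1")
  TRUE
})

#' @rdname StructuringElement-class
#' @param shape `"disc"` or `"square"`.
#' @param size kernel width in pixels.
#' @return a `StructuringElement` object.
#' @export
structuringElement <- function(shape = c("disc", "square"), size = 3)
  new("StructuringElement", shape = match.arg(shape), size = as.numeric(size))

#' Area sieve predicate
#'
#' The sieve RETAINS objects whose area satisfies the predicate (strict
#' inequality): `greater_than` keeps objects with area > threshold (removing
#' small debris), `less_than` keeps objects with area < threshold.
#'
#' @slot mode `"greater_than"` or `"less_than"`.
#' @slot areaThreshold area threshold in pixels^2 (> 0).
#' @export
setClass("SievePredicate", representation(mode = "character", areaThreshold = "numeric"))

setValidity("SievePredicate", function(object) {
  if (!object@mode %in% c("greater_than", "less_than"))
    return("mode must be 'greater_than' or 'less_than'")
  if (length(object@areaThreshold) != 1L || is.na(object@areaThreshold) ||
      object@areaThreshold <= 0)
    return("areaThreshold must be positive")
  TRUE
})

#' @rdname SievePredicate-class
#' @param mode `"greater_than"` or `"less_than"`.
#' @param areaThreshold area threshold (pixels^2).
#' @return a `SievePredicate` object.
#' @export
sievePredicate <- function(mode = c("greater_than", "less_than"), areaThreshold)
  new("SievePredicate", mode = match.arg(mode), areaThreshold = as.numeric(areaThreshold))

#' Nucleus-to-cell overlap linking specification
#'
#' A cell object is retained iff some nucleus overlaps it sufficiently:
#' with `denominator = "primary"` (the printed protocol reading, "80% of
#' primary target within secondary target") the fraction is
#' |nucleus inside cell| / |nucleus|; with `"secondary"` it is
#' |nucleus inside cell| / |cell|. The comparison is inclusive (>=) and
#' carried out in integer arithmetic.
#'
#' @slot primary name of the primary (nucleus) target.
#' @slot secondary name of the secondary (cell) target.
#' @slot overlapFraction required fraction in (0, 1].
#' @slot denominator `"primary"` or `"secondary"`.
#' @export
setClass("LinkSpec",
  representation(primary = "character", secondary = "character",
                 overlapFraction = "numeric", denominator = "character"))

setValidity("LinkSpec", function(object) {
  f <- object@overlapFraction
  if (length(f) != 1L || is.na(f) || f <= 0 || f > 1)
    return("overlapFraction must lie in (0, 1]")
  if (!object@denominator %in% c("primary", "secondary"))
    return("denominator must be 'primary' or 'secondary'")
  TRUE
})

#' @rdname LinkSpec-class
#' @param primary primary (nucleus) target name.
#' @param secondary secondary (cell) target name.
#' @param overlapFraction required overlap fraction in (0, 1].
#' @param denominator which target's area divides the intersection.
#' @return a `LinkSpec` object.
#' @export
linkSpec <- function(primary = "nuclei", secondary, overlapFraction = 0.8,
                     denominator = c("primary", "secondary"))
  new("LinkSpec", primary = primary, secondary = secondary,
      overlapFraction = as.numeric(overlapFraction),
      denominator = match.arg(denominator))

## ---------------------------------------------------------------------------
## WholeCellSet
## ---------------------------------------------------------------------------

#' Nucleated whole-cell objects of one population class
#'
#' Cell objects that survived the nucleus-overlap linking rule, relabelled
#' 1..M, with the matched nucleus recorded per object.
#'
#' @slot labels integer label map of the surviving cell objects.
#' @slot cellClass population tag, e.g. `"gfp_positive"`, `"gfp_negative"`,
#'   `"gfp"`, `"rfp"`.
#' @slot nucleusOf integer vector, one entry per object (names = object
#'   labels), giving the label of the matched nucleus in the primary target.
#' @export
setClass("WholeCellSet",
  representation(labels = "matrix", cellClass = "character", nucleusOf = "integer"))

setValidity("WholeCellSet", function(object) {
  if (!isLabelMap(object@labels)) return("labels must be a contiguous label map")
  n <- max(object@labels)
  if (length(object@nucleusOf) != n) return("nucleusOf must have one entry per object")
  if (n > 0 && !identical(names(object@nucleusOf), as.character(seq_len(n))))
    return("nucleusOf must be named by object label 1..N")
  TRUE
})

#' @rdname WholeCellSet-class
#' @param labels integer label map.
#' @param cellClass population tag.
#' @param nucleusOf named integer vector mapping object label to nucleus label.
#' @return a `WholeCellSet` object.
#' @export
WholeCellSet <- function(labels, cellClass, nucleusOf = integer(0)) {
  storage.mode(labels) <- "integer"
  nucleusOf <- as.integer(nucleusOf)
  n <- if (length(labels)) max(labels) else 0L
  if (n > 0L) names(nucleusOf) <- as.character(seq_len(n))
  new("WholeCellSet", labels = labels, cellClass = cellClass, nucleusOf = nucleusOf)
}

setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))
setGeneric("cellClass", function(x) standardGeneric("cellClass"))
setGeneric("nucleusOf", function(x) standardGeneric("nucleusOf"))
setGeneric("nObjects", function(x) standardGeneric("nObjects"))

#' @describeIn WholeCellSet label map accessor.
#' @param x a `WholeCellSet`.
#' @export
setMethod("cellLabels", "WholeCellSet", function(x) x@labels)

#' @describeIn WholeCellSet population tag accessor.
#' @export
setMethod("cellClass", "WholeCellSet", function(x) x@cellClass)

#' @describeIn WholeCellSet matched-nucleus map accessor.
#' @export
setMethod("nucleusOf", "WholeCellSet", function(x) x@nucleusOf)

#' @describeIn WholeCellSet number of whole-cell objects.
#' @export
setMethod("nObjects", "WholeCellSet", function(x) as.integer(max(x@labels, 0L)))

setMethod("show", "WholeCellSet", function(object) {
  cat(sprintf("WholeCellSet '%s': %d nucleated objects on %d x %d px\n",
              object@cellClass, nObjects(object),
              nrow(object@labels), ncol(object@labels)))
})
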