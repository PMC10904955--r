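#' Load a multi-channel field from a TIFF file
#'
#' Reads a single- or multi-plane grayscale TIFF (uint8 or uint16) and maps
#' the planes, in file order, to channel roles. Intensities are never
#' rescaled: 8-bit planes are widened into the 16-bit range with their
#' values unchanged.
#'
#' @param path path to the TIFF file.
#' @param channelMap character vector of channel roles (among `nuclear`,
#'   `pan_cell`, `gfp`, `rfp`), one per stored plane, in plane order.
#' @param pixelSize optional microns per pixel, recorded on the image.
#' @return a [MultiChannelImage-class].
#' @examples
#' f <- tempfile(fileext = ".tif")
#' writeField(MultiChannelImage(list(nuclear = matrix(7L, 4, 4))), f)
#' img <- loadField(f, "nuclear")
#' @export
loadField <- function(path, channelMap = c("nuclear", "pan_cell", "gfp"),
                      pixelSize = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!all(channelMap %in% .CHANNEL_ROLES))
    stop("unknown channel role(s) in channelMap: ",
         paste(setdiff(channelMap, .CHANNEL_ROLES), collapse = ", "), call. = FALSE)
  planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (any(vapply(planes, function(p) length(dim(p)) == 3L, logical(1))))
    stop("RGB-interleaved TIFF: split channels first (one grayscale plane per channel)",
         call. = FALSE)
  if (length(planes) != length(channelMap))
    stop(sprintf("channel map mismatch: expected %d planes, found %d",
                 length(channelMap), length(planes)), call. = FALSE)
  names(planes) <- channelMap
  MultiChannelImage(planes, pixelSize = pixelSize)
}

#' Write a multi-channel field to a 16-bit multi-plane TIFF
#'
#' Planes are stored in the order they appear on the image; reloading with
#' [loadField()] and the matching channel map reproduces the planes
#' bit-exactly.
#'
#' @param image a [MultiChannelImage-class].
#' @param path output path.
#' @return invisibly, the channel roles in stored order.
#' @export
writeField <- function(image, path) {
  stopifnot(is(image, "MultiChannelImage"))
  planes <- lapply(image@planes, function(p) p / 65535)
  tiff::writeTIFF(planes, path, bits.per.sample = 16L)
  invisible(names(image@planes))
}

#' Write a label map (or binary mask) as an integer TIFF
#'
#' Uses 16 bits per sample, or 32 when more than 65535 objects are present;
#' [readLabelMap()] reproduces the stored labels exactly in either case.
#'
#' @param labels integer label map (0 = background) or logical mask.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeLabelMap <- function(labels, path) {
  if (is.logical(labels)) labels <- labels * 1L
  .assertLabelMap(labels)
  mx <- max(labels)
  if (mx <= 65535) {
    tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  } else {
    tiff::writeTIFF(labels / (2^32 - 1), path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Read a label map written by [writeLabelMap()]
#'
#' @param path path to the label TIFF.
#' @return an integer matrix.
#' @export
readLabelMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L)
    stop("not a single-plane label TIFF: ", path, call. = FALSE)
  storage.mode(m) <- "integer"
  m
}
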