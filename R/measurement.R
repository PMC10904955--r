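#' Per-object measurements
#'
#' One record per whole-cell object: pixel area (and physical area when a
#' pixel size is known), centroid position, perimeter, form factor and
#' eccentricity. Coordinates are 0-based with origin at the top-left
#' corner; `centroid_x` is the column direction (the X position in the
#' field of view) and centroids are arithmetic means of pixel coordinates.
#'
#' The shape score is the form factor `4*pi*area / perimeter^2`
#' (1 for a perfect disc, smaller for spread or ragged objects), with the
#' perimeter estimated per object, in isolation, by the Benkrid weighted
#' boundary-step convention (straight boundary steps weigh 1, diagonal
#' steps `sqrt(2)`, corner pixels `(1+sqrt(2))/2`), which is unbiased
#' enough that digital discs score close to 1. Eccentricity comes from the
#' second central moments (0 for a disc, 1 for a line).
#'
#' @param cells a [WholeCellSet-class].
#' @param fieldId identifier of the field of view.
#' @param pixelSize optional microns per pixel; when given, `area_um2`
#'   is reported as `area_px * pixelSize^2`.
#' @return a data.frame with columns `field_id`, `class`, `object_id`,
#'   `nucleus_id`, `area_px`, `area_um2`, `centroid_x`, `centroid_y`,
#'   `perimeter_px`, `form_factor`, `eccentricity`.
#' @export
measureObjects <- function(cells, fieldId = "field1", pixelSize = NA_real_) {
  stopifnot(is(cells, "WholeCellSet"))
  lab <- cellLabels(cells)
  n <- nObjects(cells)
  cols <- c("field_id", "class", "object_id", "nucleus_id", "area_px", "area_um2",
            "centroid_x", "centroid_y", "perimeter_px", "form_factor", "eccentricity")
  if (n == 0L) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    df$field_id <- character(0); df$class <- character(0)
    return(df)
  }
  nuc <- nucleusOf(cells)
  recs <- vector("list", n)
  for (k in seq_len(n)) {
    mk <- lab == k
    area <- sum(mk)
    rows <- row(lab)[mk] - 1  # 0-based
    colsk <- col(lab)[mk] - 1
    cx <- mean(colsk); cy <- mean(rows)
    bb <- .bbox(mk, pad = 1L)
    per <- .perimeterBenkrid(mk[bb[1L]:bb[2L], bb[3L]:bb[4L], drop = FALSE])
    ff <- 4 * pi * area / per^2
    ## eccentricity of the equivalent ellipse from central moments
    mu20 <- mean((colsk - cx)^2); mu02 <- mean((rows - cy)^2)
    mu11 <- mean((colsk - cx) * (rows - cy))
    tr <- mu20 + mu02
    det2 <- sqrt(max((mu20 - mu02)^2 + 4 * mu11^2, 0))
    l1 <- (tr + det2) / 2; l2 <- (tr - det2) / 2
    ecc <- if (l1 <= 0) 0 else sqrt(max(1 - l2 / l1, 0))
    recs[[k]] <- data.frame(
      field_id = as.character(fieldId), class = cellClass(cells),
      object_id = k, nucleus_id = unname(nuc[as.character(k)]),
      area_px = area,
      area_um2 = if (is.na(pixelSize)) NA_real_ else area * pixelSize^2,
      centroid_x = cx, centroid_y = cy,
      perimeter_px = per, form_factor = ff, eccentricity = ecc,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, recs)
}

#' Per-field and across-field summaries
#'
#' Aggregates object records into the protocol's field measures: per field
#' and class, the object count and the area covered; across fields, the
#' summed count and summed area per class (results over the 5-6 fields of
#' a chip are summed, never stitched).
#'
#' @param records data.frame of object records from [measureObjects()]
#'   (possibly several fields row-bound together).
#' @return a list with `perField` (columns `field_id`, `class`, `count`,
#'   `area_covered`) and `totals` (columns `class`, `sum_count`,
#'   `sum_area_covered`).
#' @export
summarizeFields <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    return(list(
      perField = data.frame(field_id = character(0), class = character(0),
                            count = integer(0), area_covered = numeric(0)),
      totals = data.frame(class = character(0), sum_count = integer(0),
                          sum_area_covered = numeric(0))))
  }
  perField <- stats::aggregate(
    list(count = rep(1L, nrow(records)), area_covered = records$area_px),
    by = list(field_id = records$field_id, class = records$class), FUN = sum)
  perField <- perField[order(perField$field_id, perField$class), , drop = FALSE]
  rownames(perField) <- NULL
  totals <- stats::aggregate(
    list(sum_count = perField$count, sum_area_covered = perField$area_covered),
    by = list(class = perField$class), FUN = sum)
  totals <- totals[order(totals$class), , drop = FALSE]
  rownames(totals) <- NULL
  list(perField = perField, totals = totals)
}

#' Write measurement tables as CSV
#'
#' Writes the per-object table and the two summary tables with a fixed,
#' versioned column order, so runs are diffable.
#'
#' @param records per-object data.frame from [measureObjects()].
#' @param dir output directory (created if absent).
#' @param prefix filename prefix.
#' @return invisibly, the paths written.
#' @export
writeMeasurements <- function(records, dir, prefix = "chipcyte") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  s <- summarizeFields(records)
  paths <- file.path(dir, paste0(prefix, c("_objects.csv", "_fields.csv", "_totals.csv")))
  write.csv(records, paths[1L], row.names = FALSE)
  write.csv(s$perField, paths[2L], row.names = FALSE)
  write.csv(s$totals, paths[3L], row.names = FALSE)
  invisible(paths)
}
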