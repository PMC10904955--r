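#' Mask subtraction
#'
#' Set difference of two binary masks of identical shape; used to derive
#' the marker-negative population (all cells minus marker-positive cells).
#'
#' @param minuend binary mask.
#' @param subtrahend binary mask.
#' @return `minuend & !subtrahend`.
#' @export
maskSubtract <- function(minuend, subtrahend) {
  .assertMask(minuend, "minuend")
  .assertMask(subtrahend, "subtrahend")
  if (!identical(dim(minuend), dim(subtrahend)))
    stop("minuend and subtrahend must share dimensions", call. = FALSE)
  minuend & !subtrahend
}

#' Debris exclusion
#'
#' Removes every pixel belonging to a debris object from a cell mask.
#'
#' @param cells binary mask.
#' @param debris integer label map of debris objects.
#' @return a binary mask.
#' @export
excludeDebris <- function(cells, debris) {
  .assertMask(cells, "cells")
  .assertLabelMap(debris, "debris")
  if (!identical(dim(cells), dim(debris)))
    stop("cells and debris must share dimensions", call. = FALSE)
  cells & !(debris > 0)
}

#' Nucleus-to-cell overlap linking (nucleation rule)
#'
#' A cell object survives iff some nucleus satisfies the overlap rule of
#' `spec`: with the default `denominator = "primary"`, at least
#' `overlapFraction` of the nucleus' pixels lie inside the cell object
#' (inclusive `>=`; a nucleus exactly at the fraction counts). One matching
#' nucleus suffices. The comparison is integer-exact:
#' `|n ∩ c| * P >= round(f * P) * |n|` with `P = 1e6`.
#'
#' Survivors are relabelled 1..M preserving order. Each survivor records a
#' matched nucleus: matches are assigned one-to-one, greedily by descending
#' overlap fraction (ties to the lower cell then nucleus label); a survivor
#' whose matching nuclei are all claimed records its highest-fraction
#' nucleus. At fractions above 0.5 a nucleus can match at most one of the
#' disjoint cell objects, so the assignment is trivially one-to-one there.
#'
#' @param nuclei integer label map of nuclei (primary target).
#' @param cells integer label map of candidate cell objects.
#' @param spec a [LinkSpec-class].
#' @param cellClass population tag recorded on the result.
#' @return a [WholeCellSet-class].
#' @export
linkByOverlap <- function(nuclei, cells, spec = linkSpec(secondary = "cells"),
                          cellClass = "cell") {
  .assertLabelMap(nuclei, "nuclei")
  .assertLabelMap(cells, "cells")
  stopifnot(is(spec, "LinkSpec"))
  if (!identical(dim(nuclei), dim(cells)))
    stop("nuclei and cells must share dimensions", call. = FALSE)
  storage.mode(nuclei) <- "integer"
  storage.mode(cells) <- "integer"
  nC <- max(cells)
  empty <- WholeCellSet(matrix(0L, nrow(cells), ncol(cells)), cellClass)
  if (nC == 0L || max(nuclei) == 0L) return(empty)

  both <- nuclei > 0L & cells > 0L
  if (!any(both)) return(empty)
  pairs <- data.frame(n = nuclei[both], c = cells[both])
  agg <- stats::aggregate(list(inter = rep(1L, nrow(pairs))), pairs, sum)
  nArea <- .labelAreas(nuclei)
  cArea <- .labelAreas(cells)
  denom <- if (spec@denominator == "primary") nArea[agg$n] else cArea[agg$c]
  P <- 1e6
  fP <- round(spec@overlapFraction * P)
  agg$frac <- agg$inter / denom
  match_ok <- agg$inter * P >= fP * denom
  ok <- agg[match_ok, , drop = FALSE]
  if (!nrow(ok)) return(empty)

  survivors <- sort(unique(ok$c))
  ## one-to-one greedy assignment by descending fraction
  ord <- order(-ok$frac, ok$c, ok$n)
  ok <- ok[ord, , drop = FALSE]
  nucTaken <- logical(max(nuclei))
  cellNuc <- integer(nC)
  for (i in seq_len(nrow(ok))) {
    ci <- ok$c[i]; ni <- ok$n[i]
    if (cellNuc[ci] == 0L && !nucTaken[ni]) {
      cellNuc[ci] <- ni
      nucTaken[ni] <- TRUE
    }
  }
  ## leftovers keep their best (possibly shared) nucleus
  for (ci in survivors[cellNuc[survivors] == 0L]) {
    cand <- ok[ok$c == ci, , drop = FALSE]
    best <- cand[order(-cand$frac, cand$n), , drop = FALSE][1L, ]
    cellNuc[ci] <- best$n
  }

  map <- integer(nC)
  map[survivors] <- seq_along(survivors)
  lab <- cells
  sel <- lab > 0L
  lab[sel] <- map[lab[sel]]
  WholeCellSet(lab, cellClass, nucleusOf = cellNuc[survivors])
}
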