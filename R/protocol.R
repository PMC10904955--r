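## Declarative protocol engine: a ProtocolConfig is an ordered list of
## segmentation steps (each with a post-processing chain) plus overlap
## link specifications, validated before execution and executed over the
## operator modules. Two presets transcribe the chip co-culture protocols.

#' Protocol configuration
#'
#' An ordered step graph: each step segments a named target from a channel
#' (`object`, `nuclear` or `intensity` algorithm) or derives it from earlier
#' targets (`subtract`), then applies a post-processing chain (erosion,
#' nuclei-seeded clump breaking, hole filling, area sieve, restriction to
#' another target, debris exclusion). Link specifications turn cell targets
#' into nucleated whole-cell sets. Built by [protocol1Config()],
#' [protocol2Config()] or [readProtocolConfig()].
#'
#' @slot name protocol name.
#' @slot channels channel roles the protocol requires.
#' @slot steps ordered list of step specifications.
#' @slot links list of link specifications (`name`, `primary`, `secondary`,
#'   `overlapFraction`, `denominator`, `class`).
#' @slot connectivity foreground connectivity (4 or 8).
#' @slot debrisPolicy `"ignore"` (debris computed but unused) or
#'   `"exclude"` (debris pixels removed from the cell targets).
#' @slot partitionCheck character(3): two whole-cell class names and a
#'   target name whose mask must contain both, disjointly (the
#'   marker-positive / marker-negative partition); empty to skip.
#' @export
setClass("ProtocolConfig",
  representation(name = "character", channels = "character", steps = "list",
                 links = "list", connectivity = "numeric",
                 debrisPolicy = "character", partitionCheck = "character"))

setValidity("ProtocolConfig", function(object) {
  msg <- .validateConfig(object)
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ProtocolConfig", function(object) {
  cat(sprintf("ProtocolConfig '%s': channels [%s], %d steps, %d links\n",
              object@name, paste(object@channels, collapse = ", "),
              length(object@steps), length(object@links)))
  for (s in object@steps)
    cat(sprintf("  %-14s %s\n", s$name,
                if (s$kind == "segment") paste0(s$algorithm, "(", s$channel, ")")
                else paste0("subtract(", s$minuend, ", ", s$subtrahend, ")")))
})

## Structural validation: every referenced target defined by an earlier
## step, exactly one nuclear-segmentation target, links reference existing
## targets. Returns NULL or an error message.
.validateConfig <- function(cfg) {
  defined <- character(0)
  nNuclear <- 0L
  for (s in cfg@steps) {
    if (is.null(s$name) || !nzchar(s$name)) return("every step needs a name")
    if (s$name %in% defined) return(paste0("duplicate target '", s$name, "'"))
    if (s$kind == "segment") {
      if (!s$algorithm %in% c("object", "nuclear", "intensity"))
        return(paste0("unknown algorithm in step '", s$name, "'"))
      if (!s$channel %in% .CHANNEL_ROLES)
        return(paste0("unknown channel '", s$channel, "' in step '", s$name, "'"))
      if (s$algorithm == "nuclear") {
        nNuclear <- nNuclear + 1L
        if (is.null(s$params$seeds) || !s$params$seeds %in% defined)
          return(paste0("nuclear step '", s$name, "' needs an earlier seeds target"))
      }
    } else if (s$kind == "derive") {
      if (!identical(s$operation, "subtract"))
        return(paste0("unknown derive operation in step '", s$name, "'"))
      for (ref in c(s$minuend, s$subtrahend))
        if (!ref %in% defined)
          return(paste0("step '", s$name, "' references undefined target '", ref, "'"))
    } else return(paste0("unknown step kind in '", s$name, "'"))
    for (p in s$post) {
      ref <- switch(p$op, clump_break = p$second, restrict = p$to,
                    exclude_debris = p$debris, NULL)
      if (!is.null(ref) && !ref %in% defined)
        return(paste0("post op '", p$op, "' of step '", s$name,
                      "' references undefined target '", ref, "'"))
    }
    defined <- c(defined, s$name)
  }
  if (nNuclear != 1L) return("exactly one nuclear-segmentation target is required")
  for (l in cfg@links)
    for (ref in c(l$primary, l$secondary))
      if (!ref %in% defined)
        return(paste0("link '", l$name, "' references undefined target '", ref, "'"))
  if (length(cfg@partitionCheck) %in% c(0L, 3L) == FALSE)
    return("partitionCheck must be empty or length 3")
  if (!cfg@connectivity %in% c(4, 8)) return("connectivity must be 4 or 8")
  if (!cfg@debrisPolicy %in% c("ignore", "exclude"))
    return("debrisPolicy must be 'ignore' or 'exclude'")
  NULL
}

.step <- function(name, kind, ...) c(list(name = name, kind = kind), list(...))

#' Preset configuration for the GFP-positive vs GFP-negative protocol
#'
#' Transcribes the two-population co-culture protocol: a DAPI seed target
#' (kernel-based detection, binary erosion, area sieve), seed-guided nuclear
#' segmentation, intensity segmentation of the GFP-tagged cells and of all
#' phalloidin-stained cells, a debris target, derivation of the GFP-negative
#' cells by mask subtraction, and 80% nucleus-overlap linking of both
#' populations.
#'
#' Printed protocol parameters are the defaults (seed kernel 15 /
#' sensitivity 50 / erosion 16 / sieve > 20 px; nuclei minimum area 600 px /
#' sensitivity 15; overlap 80%). Values the protocol leaves unprinted are
#' exposed as arguments: intensity ranges default to automatic Otsu
#' thresholds, the cell-target erosion kernel to a disc of width 3, and the
#' cell-scale sieves to less-than 15000 / greater-than 100 px^2 (sized for
#' 20x-magnification cells; override to taste).
#'
#' @param gfpRange,panCellRange `"auto"` or a numeric `c(min, max)`.
#' @param seedKernel,seedSensitivity seed object-segmentation parameters.
#' @param seedErosion seed erosion kernel width (disc).
#' @param seedSieve seed sieve threshold (retain area > this).
#' @param nucleiMinArea,nucleiSensitivity nuclear segmentation parameters.
#' @param cellErosion erosion kernel width (disc) for the cell targets.
#' @param sieveLess,sieveGreater cell-target sieve thresholds (px^2).
#' @param debrisSieve debris = objects with area below this (px^2).
#' @param overlap required nucleus overlap fraction for linking.
#' @param debrisPolicy `"ignore"` or `"exclude"`.
#' @param connectivity 4 or 8.
#' @return a [ProtocolConfig-class].
#' @export
protocol1Config <- function(gfpRange = "auto", panCellRange = "auto",
                            seedKernel = 15, seedSensitivity = 50,
                            seedErosion = 16, seedSieve = 20,
                            nucleiMinArea = 600, nucleiSensitivity = 15,
                            cellErosion = 3, sieveLess = 15000, sieveGreater = 100,
                            debrisSieve = 100, overlap = 0.8,
                            debrisPolicy = c("ignore", "exclude"),
                            connectivity = 8) {
  debrisPolicy <- match.arg(debrisPolicy)
  cellPost <- function(restrictTo = NULL) {
    post <- list()
    if (!is.null(restrictTo))
      post <- c(post, list(list(op = "restrict", to = restrictTo)))
    post <- c(post,
      list(list(op = "erode", shape = "disc", size = cellErosion),
           list(op = "clump_break", second = "nuclei"),
           list(op = "fill_holes")))
    if (!is.null(restrictTo))
      post <- c(post, list(list(op = "restrict", to = restrictTo)))
    if (debrisPolicy == "exclude")
      post <- c(post, list(list(op = "exclude_debris", debris = "debris")))
    c(post, list(list(op = "sieve", mode = "less_than", threshold = sieveLess),
                 list(op = "sieve", mode = "greater_than", threshold = sieveGreater)))
  }
  steps <- list(
    .step("seed", "segment", channel = "nuclear", algorithm = "object",
          params = list(kernelSize = seedKernel, sensitivity = seedSensitivity),
          post = list(list(op = "erode", shape = "disc", size = seedErosion),
                      list(op = "sieve", mode = "greater_than", threshold = seedSieve))),
    .step("nuclei", "segment", channel = "nuclear", algorithm = "nuclear",
          params = list(minTargetArea = nucleiMinArea,
                        sensitivity = nucleiSensitivity, seeds = "seed"),
          post = list(list(op = "fill_holes"),
                      list(op = "sieve", mode = "less_than", threshold = sieveLess),
                      list(op = "sieve", mode = "greater_than", threshold = sieveGreater))),
    .step("debris", "segment", channel = "pan_cell", algorithm = "intensity",
          params = list(range = panCellRange),
          post = list(list(op = "sieve", mode = "less_than", threshold = debrisSieve))),
    .step("cells", "segment", channel = "pan_cell", algorithm = "intensity",
          params = list(range = panCellRange), post = cellPost()),
    .step("gfp_cells", "segment", channel = "gfp", algorithm = "intensity",
          params = list(range = gfpRange), post = cellPost(restrictTo = "cells")),
    .step("gfp_negative", "derive", operation = "subtract",
          minuend = "cells", subtrahend = "gfp_cells",
          post = list(list(op = "clump_break", second = "nuclei"),
                      list(op = "sieve", mode = "greater_than", threshold = sieveGreater))))
  links <- list(
    list(name = "whole_gfp_positive", primary = "nuclei", secondary = "gfp_cells",
         overlapFraction = overlap, denominator = "primary", class = "gfp_positive"),
    list(name = "whole_gfp_negative", primary = "nuclei", secondary = "gfp_negative",
         overlapFraction = overlap, denominator = "primary", class = "gfp_negative"))
  new("ProtocolConfig", name = "protocol1",
      channels = c("nuclear", "pan_cell", "gfp"),
      steps = steps, links = links, connectivity = connectivity,
      debrisPolicy = debrisPolicy,
      partitionCheck = c("gfp_positive", "gfp_negative", "cells"))
}

#' Preset configuration for the GFP vs RFP protocol
#'
#' Two differently tagged populations: seed and nuclei targets as in
#' [protocol1Config()], then each population segmented by intensity from its
#' own channel with the same post-processing chain, and both linked at 80%
#' nucleus overlap.
#'
#' @inheritParams protocol1Config
#' @param rfpRange `"auto"` or a numeric `c(min, max)`.
#' @return a [ProtocolConfig-class].
#' @export
protocol2Config <- function(gfpRange = "auto", rfpRange = "auto",
                            seedKernel = 15, seedSensitivity = 50,
                            seedErosion = 16, seedSieve = 20,
                            nucleiMinArea = 600, nucleiSensitivity = 15,
                            cellErosion = 3, sieveLess = 15000, sieveGreater = 100,
                            overlap = 0.8, connectivity = 8) {
  pop <- function(name, channel, range)
    .step(name, "segment", channel = channel, algorithm = "intensity",
          params = list(range = range),
          post = list(list(op = "erode", shape = "disc", size = cellErosion),
                      list(op = "clump_break", second = "nuclei"),
                      list(op = "fill_holes"),
                      list(op = "sieve", mode = "less_than", threshold = sieveLess),
                      list(op = "sieve", mode = "greater_than", threshold = sieveGreater)))
  steps <- list(
    .step("seed", "segment", channel = "nuclear", algorithm = "object",
          params = list(kernelSize = seedKernel, sensitivity = seedSensitivity),
          post = list(list(op = "erode", shape = "disc", size = seedErosion),
                      list(op = "sieve", mode = "greater_than", threshold = seedSieve))),
    .step("nuclei", "segment", channel = "nuclear", algorithm = "nuclear",
          params = list(minTargetArea = nucleiMinArea,
                        sensitivity = nucleiSensitivity, seeds = "seed"),
          post = list(list(op = "fill_holes"),
                      list(op = "sieve", mode = "less_than", threshold = sieveLess),
                      list(op = "sieve", mode = "greater_than", threshold = sieveGreater))),
    pop("rfp_cells", "rfp", rfpRange),
    pop("gfp_cells", "gfp", gfpRange))
  links <- list(
    list(name = "whole_rfp", primary = "nuclei", secondary = "rfp_cells",
         overlapFraction = overlap, denominator = "primary", class = "rfp"),
    list(name = "whole_gfp", primary = "nuclei", secondary = "gfp_cells",
         overlapFraction = overlap, denominator = "primary", class = "gfp"))
  new("ProtocolConfig", name = "protocol2",
      channels = c("nuclear", "gfp", "rfp"),
      steps = steps, links = links, connectivity = connectivity,
      debrisPolicy = "ignore", partitionCheck = character(0))
}

## ---------------------------------------------------------------------------
## YAML round trip
## ---------------------------------------------------------------------------

#' Read a protocol configuration from YAML
#'
#' The schema mirrors the [ProtocolConfig-class] slots; the two shipped
#' presets under `system.file("protocols", package = "chipcyte")` are the
#' reference examples.
#'
#' @param path YAML file path.
#' @return a [ProtocolConfig-class].
#' @export
readProtocolConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  fixRange <- function(s) {
    if (s$kind == "segment" && s$algorithm == "intensity" &&
        !identical(s$params$range, "auto"))
      s$params$range <- as.numeric(unlist(s$params$range))
    s
  }
  new("ProtocolConfig",
      name = y$name, channels = as.character(y$channels),
      steps = lapply(y$steps, fixRange),
      links = y$links,
      connectivity = as.numeric(y$connectivity),
      debrisPolicy = y$debrisPolicy,
      partitionCheck = as.character(y$partitionCheck %||% character(0)))
}

#' Write a protocol configuration to YAML
#'
#' @param config a [ProtocolConfig-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeProtocolConfig <- function(config, path) {
  stopifnot(is(config, "ProtocolConfig"))
  y <- list(name = config@name, channels = as.list(config@channels),
            steps = config@steps, links = config@links,
            connectivity = config@connectivity,
            debrisPolicy = config@debrisPolicy,
            partitionCheck = as.list(config@partitionCheck))
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------------------
## ProtocolResult
## ---------------------------------------------------------------------------

#' Result of a protocol run
#'
#' Holds every intermediate target (mask and label map), the nucleated
#' whole-cell sets per population class, the per-object measurement table,
#' the per-field / across-field summaries, and a run log (parameters and
#' package version).
#'
#' @slot protocol protocol name.
#' @slot targets named list; each entry has `$mask` and `$labels`.
#' @slot wholeCells named list of [WholeCellSet-class], keyed by class.
#' @slot objects per-object measurement data.frame.
#' @slot summary list with `perField` and `totals` data.frames.
#' @slot log run log list.
#' @export
setClass("ProtocolResult",
  representation(protocol = "character", targets = "list", wholeCells = "list",
                 objects = "data.frame", summary = "list", log = "list"))

setMethod("show", "ProtocolResult", function(object) {
  cat(sprintf("ProtocolResult '%s': targets [%s]\n", object@protocol,
              paste(names(object@targets), collapse = ", ")))
  for (w in object@wholeCells)
    cat(sprintf("  %-14s %d cells, %d px covered\n", cellClass(w), nObjects(w),
                sum(cellLabels(w) > 0L)))
})

setGeneric("targetLabels", function(x, name) standardGeneric("targetLabels"))
setGeneric("targetMask", function(x, name) standardGeneric("targetMask"))
setGeneric("wholeCells", function(x, class) standardGeneric("wholeCells"))
setGeneric("measurements", function(x) standardGeneric("measurements"))
setGeneric("fieldSummary", function(x) standardGeneric("fieldSummary"))
setGeneric("runLog", function(x) standardGeneric("runLog"))

.getTarget <- function(x, name) {
  if (!name %in% names(x@targets))
    stop("no such target: ", name, call. = FALSE)
  x@targets[[name]]
}

#' @describeIn ProtocolResult label map of a named target.
#' @param x a `ProtocolResult`.
#' @param name target name.
#' @export
setMethod("targetLabels", "ProtocolResult", function(x, name) .getTarget(x, name)$labels)

#' @describeIn ProtocolResult binary mask of a named target.
#' @export
setMethod("targetMask", "ProtocolResult", function(x, name) .getTarget(x, name)$mask)

#' @describeIn ProtocolResult whole-cell set of a population class.
#' @param class population class tag.
#' @export
setMethod("wholeCells", "ProtocolResult", function(x, class) {
  if (!class %in% names(x@wholeCells))
    stop("no whole-cell class: ", class, call. = FALSE)
  x@wholeCells[[class]]
})

#' @describeIn ProtocolResult per-object measurement table.
#' @export
setMethod("measurements", "ProtocolResult", function(x) x@objects)

#' @describeIn ProtocolResult per-field and across-field summaries.
#' @export
setMethod("fieldSummary", "ProtocolResult", function(x) x@summary)

#' @describeIn ProtocolResult run log (parameters, version).
#' @export
setMethod("runLog", "ProtocolResult", function(x) x@log)

## ---------------------------------------------------------------------------
## Engine
## ---------------------------------------------------------------------------

.currentMask <- function(state) {
  if (!is.null(state$labels)) state$labels > 0L else state$mask
}

.runStep <- function(s, image, targets, connectivity) {
  if (s$kind == "segment") {
    plane <- image@planes[[s$channel]]
    state <- switch(s$algorithm,
      object = list(mask = segmentObjects(plane,
                      objectSegParams(s$params$kernelSize, s$params$sensitivity)),
                    labels = NULL),
      nuclear = list(mask = NULL,
                     labels = segmentNuclei(plane, targets[[s$params$seeds]]$labels,
                       nuclearSegParams(s$params$minTargetArea, s$params$sensitivity))),
      intensity = {
        rng <- if (identical(s$params$range, "auto")) autoIntensityRange(plane)
               else intensityRange(s$params$range[1L], s$params$range[2L])
        list(mask = segmentIntensity(plane, rng), labels = NULL)
      })
  } else {
    m <- maskSubtract(.currentMask(targets[[s$minuend]]),
                      .currentMask(targets[[s$subtrahend]]))
    state <- list(mask = m, labels = NULL)
  }
  for (p in s$post) {
    state <- switch(p$op,
      erode = {
        se <- structuringElement(p$shape %||% "disc", p$size)
        if (is.null(state$labels)) list(mask = erodeMask(state$mask, se), labels = NULL)
        else {
          er <- erodeMask(state$labels > 0L, se)
          lab <- state$labels; lab[!er] <- 0L
          list(mask = NULL, labels = .relabelRaster(lab))
        }
      },
      clump_break = list(mask = NULL,
        labels = breakClumps(.currentMask(state), targets[[p$second]]$labels,
                             distanceTo = p$distanceTo %||% "region",
                             connectivity = connectivity)),
      fill_holes = if (is.null(state$labels))
          list(mask = fillHoles(state$mask), labels = NULL)
        else list(mask = NULL, labels = fillHolesLabels(state$labels)),
      sieve = {
        lab <- if (is.null(state$labels)) labelComponents(state$mask, connectivity)
               else state$labels
        list(mask = NULL,
             labels = sieveObjects(lab, sievePredicate(p$mode, p$threshold)))
      },
      restrict = {
        other <- .currentMask(targets[[p$to]])
        if (is.null(state$labels)) list(mask = state$mask & other, labels = NULL)
        else {
          lab <- state$labels; lab[!other] <- 0L
          list(mask = NULL, labels = .relabelRaster(lab))
        }
      },
      exclude_debris = {
        deb <- targets[[p$debris]]$labels
        if (is.null(state$labels)) {
          list(mask = excludeDebris(state$mask, deb), labels = NULL)
        } else {
          lab <- state$labels; lab[deb > 0L] <- 0L
          list(mask = NULL, labels = .relabelRaster(lab))
        }
      },
      stop("unknown post op: ", p$op, call. = FALSE))
  }
  if (is.null(state$labels)) state$labels <- labelComponents(state$mask, connectivity)
  state$mask <- state$labels > 0L
  state
}

## In-engine invariant checks; violation is a bug, so stop().
.checkInvariants <- function(cfg, targets, wholeCells) {
  for (l in cfg@links) {
    w <- wholeCells[[l$class]]
    if (nObjects(w) == 0L) next
    nuclei <- targets[[l$primary]]$labels
    nArea <- .labelAreas(nuclei)
    nuc <- nucleusOf(w)
    lab <- cellLabels(w)
    P <- 1e6; fP <- round(l$overlapFraction * P)
    for (k in seq_len(nObjects(w))) {
      inter <- sum(nuclei == nuc[[as.character(k)]] & lab == k)
      denom <- if (identical(l$denominator, "secondary")) sum(lab == k)
               else nArea[nuc[[as.character(k)]]]
      if (!(inter * P >= fP * denom))
        stop("internal error: nucleation rule violated for object ", k,
             " of class ", l$class, call. = FALSE)
    }
  }
  if (length(cfg@partitionCheck) == 3L) {
    a <- cellLabels(wholeCells[[cfg@partitionCheck[1L]]]) > 0L
    b <- cellLabels(wholeCells[[cfg@partitionCheck[2L]]]) > 0L
    within <- targets[[cfg@partitionCheck[3L]]]$mask
    if (any(a & b)) stop("internal error: class pixel sets overlap", call. = FALSE)
    if (any(a & !within) || any(b & !within))
      stop("internal error: class pixels outside the cell mask", call. = FALSE)
  }
  invisible(TRUE)
}

#' Run a protocol over one field
#'
#' Validates the configuration, checks the image provides the required
#' channel roles, executes each step's segmentation and post-processing
#' chain, links the cell targets to nuclei, asserts the protocol invariants
#' (nucleation rule per object; for the two-class protocol, that the class
#' pixel sets partition within the cell mask), and emits measurements.
#' Fully deterministic: identical image and config give identical results.
#'
#' @param image a [MultiChannelImage-class].
#' @param config a [ProtocolConfig-class].
#' @param fieldId identifier used in the measurement tables.
#' @return a [ProtocolResult-class].
#' @export
runProtocol <- function(image, config, fieldId = "field1") {
  stopifnot(is(image, "MultiChannelImage"), is(config, "ProtocolConfig"))
  msg <- .validateConfig(config)
  if (!is.null(msg)) stop("invalid protocol config: ", msg, call. = FALSE)
  missing <- setdiff(config@channels, names(image@planes))
  if (length(missing))
    stop("image lacks required channel role(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  targets <- list()
  for (s in config@steps) {
    state <- tryCatch(.runStep(s, image, targets, as.integer(config@connectivity)),
                      error = function(e)
                        stop(sprintf("step '%s' failed: %s", s$name,
                                     conditionMessage(e)), call. = FALSE))
    targets[[s$name]] <- state
  }
  wholeCells <- list()
  for (l in config@links) {
    spec <- linkSpec(primary = l$primary, secondary = l$secondary,
                     overlapFraction = l$overlapFraction,
                     denominator = l$denominator %||% "primary")
    wholeCells[[l$class]] <- linkByOverlap(targets[[l$primary]]$labels,
                                           targets[[l$secondary]]$labels,
                                           spec, cellClass = l$class)
  }
  .checkInvariants(config, targets, wholeCells)
  objects <- do.call(rbind, lapply(wholeCells, measureObjects,
                                   fieldId = fieldId, pixelSize = image@pixelSize))
  if (is.null(objects)) objects <- measureObjects(
    WholeCellSet(matrix(0L, nrow(image@planes[[1L]]), ncol(image@planes[[1L]])), "none"),
    fieldId = fieldId)
  rownames(objects) <- NULL
  new("ProtocolResult", protocol = config@name, targets = targets,
      wholeCells = wholeCells, objects = objects,
      summary = summarizeFields(objects),
      log = list(protocol = config@name, fieldId = fieldId,
                 connectivity = config@connectivity,
                 debrisPolicy = config@debrisPolicy,
                 packageVersion = as.character(utils::packageVersion("chipcyte"))))
}

#' @rdname runProtocol
#' @param ... passed to [protocol1Config()] / [protocol2Config()].
#' @export
runProtocol1 <- function(image, fieldId = "field1", ...)
  runProtocol(image, protocol1Config(...), fieldId = fieldId)

#' @rdname runProtocol
#' @export
runProtocol2 <- function(image, fieldId = "field1", ...)
  runProtocol(image, protocol2Config(...), fieldId = fieldId)
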