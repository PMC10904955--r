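## Synthetic chip-field generator: renders multi-channel fluorescence
## fields that emulate the microfluidic co-culture images (bright rounded
## nuclei on a dark background, cytoplasmic pan-cell stain, tagged
## subpopulations in their own channels, dark trapezoidal posts flanking
## the field, Poisson-Gaussian camera noise, deliberate touching-cell
## clumps) together with ground-truth instance masks.

## Fixed rendering amplitudes (counts over background); the snr knob sets
## the noise level relative to the nuclear amplitude.
.AMP_NUCLEAR <- 5000
.AMP_TAG <- 5000       # GFP / RFP channels
.AMP_CYTO <- 3000      # pan-cell stain over cytoplasm
.AMP_CYTO_NUC <- 1000  # residual pan-cell signal over the nucleus
.POST_DEPTH <- 40      # px the posts protrude into the field
.RENDER_BLUR <- 2      # Gaussian sigma of the optical blur, px

#' Scene parameters for the synthetic field generator
#'
#' Defaults describe the study condition used throughout the test suite:
#' a 512 x 512 field, 30 cells of which 40% are GFP-tagged, nucleus radii
#' 14-18 px (areas comfortably above the 600 px^2 nuclear minimum),
#' cytoplasm twice the nucleus radius, 20% of cells placed as touching
#' pairs, peak-signal to background-noise ratio 10, trapezoidal posts with
#' a 100 px base and 100 px spacing (the chip's 100 um / 100 um post array
#' at ~1 um/px), and a 500-count background offset.
#'
#' @slot height,width field size in pixels.
#' @slot nCells number of cells to place.
#' @slot gfpFraction,rfpFraction fractions of cells tagged GFP / RFP; the
#'   tagged counts are `floor(n * f + 0.5)`; remaining cells are untagged
#'   (pan-cell stain only).
#' @slot nucleusRadiusRange min/max nucleus equivalent radius, px.
#' @slot cytoplasmScale cell radius as a multiple of the nucleus radius.
#' @slot clumpProbability fraction of cells placed touching a neighbour.
#' @slot snr (peak nuclear amplitude) / (background noise sd).
#' @slot postBase,postSpacing trapezoid base length and gap, px.
#' @slot backgroundLevel background offset, counts.
#' @slot rngSeed integer seed; fields are bit-reproducible given the seed.
#' @export
setClass("SceneParams",
  representation(height = "numeric", width = "numeric", nCells = "numeric",
                 gfpFraction = "numeric", rfpFraction = "numeric",
                 nucleusRadiusRange = "numeric", cytoplasmScale = "numeric",
                 clumpProbability = "numeric", snr = "numeric",
                 postBase = "numeric", postSpacing = "numeric",
                 backgroundLevel = "numeric", rngSeed = "numeric"))

setValidity("SceneParams", function(object) {
  f <- c(object@gfpFraction, object@rfpFraction, object@clumpProbability)
  if (any(f < 0 | f > 1)) return("fractions must lie in [0, 1]")
  if (object@gfpFraction + object@rfpFraction > 1)
    return("gfpFraction + rfpFraction must not exceed 1")
  if (object@snr <= 0) return("snr must be positive")
  if (object@nCells < 0) return("nCells must be non-negative")
  if (length(object@nucleusRadiusRange) != 2L ||
      any(object@nucleusRadiusRange <= 0) ||
      diff(object@nucleusRadiusRange) < 0)
    return("nucleusRadiusRange must be increasing and positive")
  if (object@height < 32 || object@width < 32) return("field must be at least 32 x 32")
  TRUE
})

#' @rdname SceneParams-class
#' @param height,width field size in pixels.
#' @param nCells number of cells.
#' @param gfpFraction,rfpFraction tagged fractions.
#' @param nucleusRadiusRange numeric length-2, px.
#' @param cytoplasmScale cell/nucleus radius ratio.
#' @param clumpProbability fraction of cells in touching pairs.
#' @param snr peak-signal to background-noise ratio.
#' @param postBase,postSpacing post geometry, px.
#' @param backgroundLevel background offset, counts.
#' @param rngSeed integer seed.
#' @return a `SceneParams` object.
#' @export
sceneParams <- function(height = 512, width = 512, nCells = 30,
                        gfpFraction = 0.4, rfpFraction = 0,
                        nucleusRadiusRange = c(14, 18), cytoplasmScale = 2,
                        clumpProbability = 0.2, snr = 10,
                        postBase = 100, postSpacing = 100,
                        backgroundLevel = 500, rngSeed = 1)
  new("SceneParams", height = height, width = width, nCells = nCells,
      gfpFraction = gfpFraction, rfpFraction = rfpFraction,
      nucleusRadiusRange = as.numeric(nucleusRadiusRange),
      cytoplasmScale = cytoplasmScale, clumpProbability = clumpProbability,
      snr = snr, postBase = postBase, postSpacing = postSpacing,
      backgroundLevel = backgroundLevel, rngSeed = rngSeed)

#' Ground truth for a synthetic field
#'
#' @slot nucleusLabels integer label map of true nuclei (label = cell id).
#' @slot cellLabels integer label map of true cells; each nucleus lies
#'   inside its cell; overlapping cytoplasm resolved to the nearer centre.
#' @slot classOf character vector, one tag per cell
#'   (`"gfp"`, `"rfp"` or `"negative"`).
#' @slot centroids n x 2 matrix of cell centres (columns `x`, `y`; 0-based).
#' @export
setClass("GroundTruth",
  representation(nucleusLabels = "matrix", cellLabels = "matrix",
                 classOf = "character", centroids = "matrix"))

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d cells (%s)\n", length(object@classOf),
              paste(sprintf("%s=%d", names(table(object@classOf)),
                            table(object@classOf)), collapse = ", ")))
})

setGeneric("truthClasses", function(x) standardGeneric("truthClasses"))

#' @describeIn GroundTruth per-cell class tags.
#' @param x a `GroundTruth`.
#' @export
setMethod("truthClasses", "GroundTruth", function(x) x@classOf)

## Pixels inside a rotated ellipse, within a bounding-box crop.
.ellipseMask <- function(nr, nc, cy, cx, a, b, theta) {
  r0 <- max(1L, floor(cy - a)); r1 <- min(nr, ceiling(cy + a))
  c0 <- max(1L, floor(cx - a)); c1 <- min(nc, ceiling(cx + a))
  rows <- r0:r1; cols <- c0:c1
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  list(rows = rows, cols = cols, inside = inside)
}

## Trapezoidal post mask: posts protrude from the left and right field
## edges; base `base` px along the edge, top 60% of base, depth .POST_DEPTH.
.postMask <- function(nr, nc, base, spacing) {
  m <- matrix(FALSE, nr, nc)
  depth <- min(.POST_DEPTH, nc %/% 8L)
  if (depth < 2L || base < 2L) return(m)
  top <- 0.6 * base
  period <- base + spacing
  cols <- seq_len(depth)
  halfw <- (base - (base - top) * (cols - 1) / max(depth - 1, 1)) / 2
  starts <- seq(1 - base, nr, by = period)
  for (s in starts) {
    centre <- s + base / 2
    for (j in cols) {
      rows <- max(1, ceiling(centre - halfw[j])):min(nr, floor(centre + halfw[j]))
      if (length(rows) && rows[1] <= rows[length(rows)]) {
        m[rows, j] <- TRUE
        m[rows, nc - j + 1L] <- TRUE
      }
    }
  }
  m
}

#' Generate a synthetic multi-channel chip field with ground truth
#'
#' Places cells (dart throwing with a minimum-spacing rule; a
#' `clumpProbability` fraction is deliberately placed as touching pairs at
#' 0.9x the cytoplasm-radius sum, so cytoplasm clumps while nuclei stay
#' separate), renders nuclei, cytoplasm and tagged-cell signals as blurred
#' ellipses, zeroes the trapezoidal post regions, and applies
#' Poisson-Gaussian noise calibrated so that
#' (peak nuclear amplitude) / sd(background) equals `snr`. The output is
#' fully determined by `rngSeed`; the global RNG state is left untouched.
#'
#' @param params a [SceneParams-class].
#' @return a list with `image` (a [MultiChannelImage-class] with `nuclear`,
#'   `pan_cell`, `gfp` and `rfp` planes) and `truth`
#'   (a [GroundTruth-class]).
#' @examples
#' f <- generateField(sceneParams(height = 128, width = 128, nCells = 2,
#'                                postBase = 40, postSpacing = 40, rngSeed = 7))
#' table(truthClasses(f$truth))
#' @export
generateField <- function(params = sceneParams()) {
  stopifnot(is(params, "SceneParams"))
  .withSeed(params@rngSeed, .generateFieldImpl(params))
}

.generateFieldImpl <- function(params) {
  nr <- as.integer(params@height); nc <- as.integer(params@width)
  n <- as.integer(params@nCells)
  posts <- .postMask(nr, nc, params@postBase, params@postSpacing)
  depth <- min(.POST_DEPTH, nc %/% 8L)

  rnRange <- params@nucleusRadiusRange
  cs <- params@cytoplasmScale
  nPairs <- as.integer(round(n * params@clumpProbability)) %/% 2L
  nAnchor <- n - nPairs

  cx <- cy <- rn <- rc <- theta <- ecc <- numeric(0)
  propose <- function() {
    r <- runif(1, rnRange[1L], rnRange[2L])
    rcand <- r * cs
    if (depth + rcand + 4 >= nc - depth - rcand - 4 || rcand + 4 >= nr - rcand - 4)
      return(NULL)
    list(rn = r, rc = rcand,
         x = runif(1, depth + rcand + 4, nc - depth - rcand - 4),
         y = runif(1, rcand + 4, nr - rcand - 4))
  }
  fits <- function(x, y, rcand, factor = 0.8) {
    length(cx) == 0L || all(sqrt((cx - x)^2 + (cy - y)^2) >= factor * (rc + rcand))
  }
  attempts <- 0L; maxAttempts <- 800L * max(n, 1L)
  bump <- function() {
    attempts <<- attempts + 1L
    if (attempts > maxAttempts)
      stop("field too small to place ", n, " cells at the required spacing",
           call. = FALSE)
  }
  addCell <- function(p) {
    cx <<- c(cx, p$x); cy <<- c(cy, p$y); rn <<- c(rn, p$rn); rc <<- c(rc, p$rc)
  }
  ## touching pairs are placed first, while the field is still sparse
  for (i in seq_len(nPairs)) {
    repeat {
      bump()
      p <- propose()
      if (is.null(p) || !fits(p$x, p$y, p$rc)) next
      ## find a partner position around the anchor
      partner <- NULL
      for (try in seq_len(60L)) {
        r <- runif(1, rnRange[1L], rnRange[2L]); rcand <- r * cs
        ang <- runif(1, 0, 2 * pi)
        d <- 0.9 * (p$rc + rcand)
        x <- p$x + d * cos(ang); y <- p$y + d * sin(ang)
        inb <- x > depth + rcand + 4 && x < nc - depth - rcand - 4 &&
               y > rcand + 4 && y < nr - rcand - 4
        if (inb && fits(x, y, rcand)) {
          partner <- list(x = x, y = y, rn = r, rc = rcand)
          break
        }
      }
      if (!is.null(partner)) {
        addCell(p); addCell(partner)
        break
      }
    }
  }
  ## remaining cells by plain dart throwing
  while (length(cx) < n) {
    bump()
    p <- propose()
    if (is.null(p)) next
    if (fits(p$x, p$y, p$rc)) addCell(p)
  }
  theta <- runif(n, 0, 2 * pi)
  ecc <- runif(n, 0, 0.6)

  ## class assignment: deterministic rounded counts, random membership
  nGfp <- floor(n * params@gfpFraction + 0.5)
  nRfp <- floor(n * params@rfpFraction + 0.5)
  classOf <- rep("negative", n)
  if (n > 0L) {
    ord <- sample.int(n)
    if (nGfp > 0L) classOf[ord[seq_len(nGfp)]] <- "gfp"
    if (nRfp > 0L) classOf[ord[nGfp + seq_len(nRfp)]] <- "rfp"
  }

  nucLab <- matrix(0L, nr, nc)
  cellLab <- matrix(0L, nr, nc)
  bestD2 <- matrix(Inf, nr, nc)
  sigNuc <- matrix(0, nr, nc); sigCyto <- matrix(0, nr, nc)
  sigGfp <- matrix(0, nr, nc); sigRfp <- matrix(0, nr, nc)
  shape <- function(i) {
    s <- (1 - ecc[i]^2)^(1 / 4)
    c(a = rn[i] / s, b = rn[i] * s)
  }
  for (i in seq_len(n)) {
    ab <- shape(i)
    nucE <- .ellipseMask(nr, nc, cy[i], cx[i], ab["a"], ab["b"], theta[i])
    celE <- .ellipseMask(nr, nc, cy[i], cx[i], cs * ab["a"], cs * ab["b"], theta[i])
    ## cell label: nearest centre wins in overlaps
    rows <- celE$rows; cols <- celE$cols
    d2 <- outer((rows - cy[i])^2, rep(1, length(cols))) +
          outer(rep(1, length(rows)), (cols - cx[i])^2)
    blockLab <- cellLab[rows, cols, drop = FALSE]
    blockD2 <- bestD2[rows, cols, drop = FALSE]
    upd <- celE$inside & (d2 < blockD2)
    blockLab[upd] <- i; blockD2[upd] <- d2[upd]
    cellLab[rows, cols] <- blockLab
    bestD2[rows, cols] <- blockD2
    nucLab[nucE$rows, nucE$cols][nucE$inside] <- i
    ## signals
    nucBlock <- matrix(0, length(nucE$rows), length(nucE$cols))
    nucBlock[nucE$inside] <- 1
    sigNuc[nucE$rows, nucE$cols] <- pmax(sigNuc[nucE$rows, nucE$cols],
                                         .AMP_NUCLEAR * nucBlock)
    celBlock <- matrix(0, length(rows), length(cols))
    celBlock[celE$inside] <- .AMP_CYTO
    sigCyto[rows, cols] <- pmax(sigCyto[rows, cols], celBlock)
    if (classOf[i] %in% c("gfp", "rfp")) {
      tagBlock <- matrix(0, length(rows), length(cols))
      tagBlock[celE$inside] <- .AMP_TAG
      if (classOf[i] == "gfp")
        sigGfp[rows, cols] <- pmax(sigGfp[rows, cols], tagBlock)
      else
        sigRfp[rows, cols] <- pmax(sigRfp[rows, cols], tagBlock)
    }
  }
  ## pan-cell stain is cytoplasmic: residual level over the nucleus
  sigCyto[nucLab > 0L] <- .AMP_CYTO_NUC

  blur <- function(x) if (.RENDER_BLUR > 0) EBImage::gblur(x, .RENDER_BLUR) else x
  noise <- function(signal) {
    lambda <- params@backgroundLevel + pmax(blur(signal), 0)
    sdTot <- .AMP_NUCLEAR / params@snr
    readSd <- sqrt(max(sdTot^2 - params@backgroundLevel, 0))
    v <- rpois(length(lambda), lambda) + rnorm(length(lambda), 0, readSd)
    m <- matrix(pmin(pmax(round(v), 0), 65535), nr, nc)
    m[posts] <- 0
    storage.mode(m) <- "integer"
    m
  }
  planes <- list(nuclear = noise(sigNuc), pan_cell = noise(sigCyto),
                 gfp = noise(sigGfp), rfp = noise(sigRfp))
  centroids <- cbind(x = cx - 1, y = cy - 1)  # 0-based convention
  list(image = MultiChannelImage(planes),
       truth = new("GroundTruth", nucleusLabels = nucLab, cellLabels = cellLab,
                   classOf = classOf, centroids = centroids))
}

#' Score a protocol result against generator ground truth
#'
#' Matches detected whole-cell objects to truth cells per population class:
#' a detected object is a candidate match for the truth cell whose region
#' contains the centroid of the detected object's nucleus; candidates are
#' made one-to-one greedily by descending pixel overlap with the truth
#' cell. Reports detection precision, recall and F1 (precision of an empty
#' detection set is reported as 0 and flagged), the signed count error and
#' the detected/truth area ratio, per class.
#'
#' @param result a [ProtocolResult-class].
#' @param truth a [GroundTruth-class] for the same field.
#' @param classMap named character vector mapping result classes to truth
#'   classes; the default covers both protocols
#'   (`gfp_positive`/`gfp` -> `gfp`, `rfp` -> `rfp`,
#'   `gfp_negative` -> `negative`).
#' @return a data.frame, one row per result class.
#' @export
scoreAgainstTruth <- function(result, truth,
                              classMap = c(gfp_positive = "gfp", gfp = "gfp",
                                           rfp = "rfp", gfp_negative = "negative")) {
  stopifnot(is(result, "ProtocolResult"), is(truth, "GroundTruth"))
  if (!identical(dim(truth@cellLabels), dim(cellLabels(result@wholeCells[[1L]]))))
    stop("result and truth field shapes differ", call. = FALSE)
  nuclei <- result@targets$nuclei$labels
  rows <- lapply(names(result@wholeCells), function(rc) {
    w <- result@wholeCells[[rc]]
    tc <- classMap[[rc]]
    truthIds <- which(truth@classOf == tc)
    nTruth <- length(truthIds)
    nDet <- nObjects(w)
    lab <- cellLabels(w)
    cand <- NULL
    if (nDet > 0L) {
      nuc <- nucleusOf(w)
      for (k in seq_len(nDet)) {
        sel <- nuclei == nuc[[as.character(k)]]
        if (!any(sel)) next
        cr <- round(mean(row(nuclei)[sel])); cc <- round(mean(col(nuclei)[sel]))
        tid <- truth@cellLabels[min(max(cr, 1), nrow(lab)), min(max(cc, 1), ncol(lab))]
        if (tid > 0L && tid %in% truthIds) {
          ov <- sum(lab == k & truth@cellLabels == tid)
          cand <- rbind(cand, c(k = k, tid = tid, ov = ov))
        }
      }
    }
    matched <- 0L
    if (!is.null(cand)) {
      cand <- cand[order(-cand[, "ov"], cand[, "k"]), , drop = FALSE]
      usedK <- usedT <- integer(0)
      for (j in seq_len(nrow(cand))) {
        if (cand[j, "k"] %in% usedK || cand[j, "tid"] %in% usedT) next
        usedK <- c(usedK, cand[j, "k"]); usedT <- c(usedT, cand[j, "tid"])
        matched <- matched + 1L
      }
    }
    detArea <- sum(lab > 0L)
    truthArea <- sum(truth@cellLabels %in% truthIds)
    precision <- if (nDet > 0L) matched / nDet else 0
    recall <- if (nTruth > 0L) matched / nTruth else NA_real_
    f1 <- if (nDet + nTruth == 0L) NA_real_
          else if (precision + max(recall, 0, na.rm = TRUE) == 0) 0
          else 2 * precision * recall / (precision + recall)
    data.frame(class = rc, truth_class = tc, n_truth = nTruth, n_detected = nDet,
               matched = matched, precision = precision, recall = recall, f1 = f1,
               count_error = nDet - nTruth,
               area_ratio = if (truthArea > 0) detArea / truthArea else NA_real_,
               precision_defined = nDet > 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
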