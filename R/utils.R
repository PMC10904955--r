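## Internal numerical helpers shared across modules. All are deterministic
## and operate on plain matrices.

## Shift a matrix by (dr, dc), padding with `fill`.
.shift <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

## Centred structuring-element footprint as a 0/1 matrix. Even widths are
## realised as the symmetric footprint of radius size/2 (exact Euclidean
## disc for shape "disc").
.seFootprint <- function(se) {
  s <- se@size
  if (s %% 2 == 1) { r <- (s - 1) / 2 } else { r <- s / 2 }
  w <- 2 * r + 1
  if (se@shape == "square" && s %% 2 == 1) {
    return(matrix(1, s, s))
  }
  if (se@shape == "square") {
    return(matrix(1, w, w))
  }
  off <- seq(-r, r)
  d2 <- outer(off^2, off^2, "+")
  (d2 <= r^2 + 1e-9) * 1
}

## Binary erosion with out-of-bounds treated as background: pad, erode
## with EBImage (which replicates borders), crop.
.binErode <- function(mask, kern) {
  pr <- (nrow(kern) - 1L) %/% 2L
  pc <- (ncol(kern) - 1L) %/% 2L
  nr <- nrow(mask); nc <- ncol(mask)
  padded <- matrix(0, nr + 2L * pr, nc + 2L * pc)
  padded[pr + seq_len(nr), pc + seq_len(nc)] <- mask * 1
  er <- EBImage::erode(padded, kern)
  er[pr + seq_len(nr), pc + seq_len(nc), drop = FALSE] > 0.5
}

## Binary dilation with out-of-bounds treated as background.
.binDilate <- function(mask, kern) {
  pr <- (nrow(kern) - 1L) %/% 2L
  pc <- (ncol(kern) - 1L) %/% 2L
  nr <- nrow(mask); nc <- ncol(mask)
  padded <- matrix(0, nr + 2L * pr, nc + 2L * pc)
  padded[pr + seq_len(nr), pc + seq_len(nc)] <- mask * 1
  di <- EBImage::dilate(padded, kern)
  di[pr + seq_len(nr), pc + seq_len(nc), drop = FALSE] > 0.5
}

## Union-find over integer ids 1..n.
.ufFind <- function(parent, i) {
  while (parent[i] != i) { parent[i] <- parent[parent[i]]; i <- parent[i] }
  i
}

## Connected-component labelling. EBImage::bwlabel is the 4-connectivity
## engine; 8-connectivity merges diagonally adjacent 4-components with
## union-find. Labels are then renumbered 1..N in row-major raster order
## of each component's first pixel (origin top-left).
.labelCC <- function(mask, connectivity = 8L) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(mask * 1)
  storage.mode(lab) <- "integer"
  if (connectivity == 8L) {
    n <- max(lab)
    parent <- seq_len(n)
    for (sh in list(c(1L, 1L), c(1L, -1L))) {
      nb <- .shift(lab, sh[1L], sh[2L], 0L)
      sel <- lab > 0L & nb > 0L & lab != nb
      if (any(sel)) {
        prs <- unique(cbind(lab[sel], nb[sel]))
        for (i in seq_len(nrow(prs))) {
          a <- .ufFind(parent, prs[i, 1L]); b <- .ufFind(parent, prs[i, 2L])
          if (a != b) parent[max(a, b)] <- min(a, b)
        }
      }
    }
    root <- vapply(seq_len(n), function(i) .ufFind(parent, i), integer(1))
    lab[lab > 0L] <- root[lab[lab > 0L]]
  }
  .relabelRaster(lab)
}

## Renumber a label map so labels are 1..N ordered by each label's first
## pixel in row-major raster order (top-left first, x = column).
.relabelRaster <- function(lab) {
  storage.mode(lab) <- "integer"
  idx <- which(lab > 0L)
  if (!length(idx)) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  r <- (idx - 1L) %% nr
  cc <- (idx - 1L) %/% nr
  raster <- r * nc + cc  # row-major position
  first <- tapply(raster, lab[idx], min)
  ord <- as.integer(names(first))[order(first)]
  map <- integer(max(lab))
  map[ord] <- seq_along(ord)
  lab[idx] <- map[lab[idx]]
  lab
}

## Per-label pixel areas; returns integer vector indexed by label 1..N.
.labelAreas <- function(lab) {
  n <- max(lab, 0L)
  if (n == 0L) return(integer(0))
  tabulate(lab[lab > 0L], nbins = n)
}

## Squared Euclidean distance from every pixel to the nearest pixel of
## `obj` (a logical matrix with at least one TRUE), as exact integers.
.sqDistTo <- function(obj) {
  d <- EBImage::distmap(1 - obj)
  round(d * d)
}

## Assign each TRUE pixel of `mask` the label of the nearest object in
## `seeds` (exact Euclidean distance to the nearest seed pixel, or to seed
## centroids when distanceTo = "centroid"); ties go to the lower seed label.
## Returns a matrix with the ORIGINAL seed labels (not renumbered); pixels
## outside mask are 0. Pixels of mask are all assigned (global nearest).
.nearestSeedAssign <- function(mask, seeds, distanceTo = "region") {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  labs <- sort(unique(seeds[seeds > 0L]))
  if (!length(labs) || !any(mask)) return(out)
  best <- matrix(Inf, nr, nc)
  if (distanceTo == "centroid") {
    rowI <- row(mask); colI <- col(mask)
  }
  for (k in labs) {
    if (distanceTo == "region") {
      d2 <- .sqDistTo(seeds == k)
    } else {
      sel <- seeds == k
      cr <- mean(rowI[sel]); cc <- mean(colI[sel])
      d2 <- (rowI - cr)^2 + (colI - cc)^2
    }
    upd <- mask & (d2 < best)  # strict: ties keep the earlier (lower) label
    out[upd] <- as.integer(k)
    best[upd] <- d2[upd]
  }
  out
}

## Box mean filter of width k (odd), replicate boundary.
.meanFilter <- function(plane, k) {
  kern <- matrix(1 / (k * k), k, k)
  EBImage::filter2(plane, kern, boundary = "replicate")
}

## Median filter of the given radius on a 16-bit-scaled plane.
.medianFilter16 <- function(plane, radius) {
  EBImage::medianFilter(plane / 65535, radius) * 65535
}

## Otsu threshold on an integer-valued plane (0..65535): returns the grey
## level t maximising between-class variance of the split {<= t} vs {> t};
## ties resolved to the lowest t. Deterministic, histogram-based.
.otsuThreshold <- function(plane) {
  v <- as.integer(plane)
  h <- tabulate(v + 1L, nbins = 65536L)
  nz <- which(h > 0L)
  if (length(nz) < 2L) return(max(0L, nz[1L] - 1L))
  lev <- nz - 1L
  p <- h[nz] / sum(h)
  w <- cumsum(p)
  mu <- cumsum(p * lev)
  muT <- mu[length(mu)]
  denom <- w * (1 - w)
  bcv <- ifelse(denom > 0, (muT * w - mu)^2 / denom, -Inf)
  bcv <- bcv[-length(bcv)]
  lev[which.max(bcv)]
}

## Per-object perimeter by the Benkrid weighted boundary-step estimator
## (the convention scikit-image's `perimeter` uses): border pixels are
## classified by their border-neighbour pattern and weighted 1, sqrt(2) or
## (1+sqrt(2))/2. Computed per object on the object's own mask in isolation.
.perimeterBenkrid <- function(mask) {
  m <- mask * 1
  ## 4-connected erosion with zero border
  er <- m
  for (sh in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L)))
    er <- er * .shift(m, sh[1L], sh[2L], 0)
  border <- m - er
  code <- border
  for (sh in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L)))
    code <- code + 2 * .shift(border, sh[1L], sh[2L], 0)
  for (sh in list(c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)))
    code <- code + 10 * .shift(border, sh[1L], sh[2L], 0)
  code <- code * border  # only border pixels contribute
  w <- numeric(50)
  w[c(5, 7, 15, 17, 25, 27) + 1] <- 1
  w[c(21, 33) + 1] <- sqrt(2)
  w[c(13, 23) + 1] <- (1 + sqrt(2)) / 2
  cnt <- tabulate(code[code > 0] + 1L, nbins = 50L)
  sum(cnt * w)
}

## Bounding box (rmin, rmax, cmin, cmax) of TRUE pixels, with `pad` margin.
.bbox <- function(mask, pad = 0L) {
  idx <- which(mask, arr.ind = TRUE)
  c(max(1L, min(idx[, 1L]) - pad), min(nrow(mask), max(idx[, 1L]) + pad),
    max(1L, min(idx[, 2L]) - pad), min(ncol(mask), max(idx[, 2L]) + pad))
}

## Evaluate an expression with a temporarily seeded RNG, restoring any
## pre-existing global .Random.seed afterwards (no global state leaks).
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}
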