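# Independent brute-force oracles: pure-R per-pixel loops, deliberately
# naive, sharing no code with the implementation.

rand_mask <- function(nr, nc, p = 0.3) matrix(runif(nr * nc) < p, nr, nc)

# flood-fill connected-component labelling (stack-based), labels renumbered
# by first pixel in row-major raster order
bf_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  nbr <- if (connectivity == 8)
    list(c(-1,-1),c(-1,0),c(-1,1),c(0,-1),c(0,1),c(1,-1),c(1,0),c(1,1))
  else list(c(-1,0),c(1,0),c(0,-1),c(0,1))
  # rows outer / cols inner = row-major raster order for first pixels
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    cur <- cur + 1L
    stack <- list(c(r0, c0))
    lab[r0, c0] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (d in nbr) {
        rr <- p[1] + d[1]; cc <- p[2] + d[2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# per-pixel erosion: pixel kept iff every offset of the footprint lands
# in-bounds on a foreground pixel (out-of-bounds = background)
bf_erode <- function(mask, footprint) {
  nr <- nrow(mask); nc <- ncol(mask)
  kr <- (nrow(footprint) - 1) / 2; kc <- (ncol(footprint) - 1) / 2
  offs <- which(footprint > 0, arr.ind = TRUE)
  offs[, 1] <- offs[, 1] - kr - 1; offs[, 2] <- offs[, 2] - kc - 1
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    keep <- TRUE
    for (i in seq_len(nrow(offs))) {
      rr <- r + offs[i, 1]; cc <- c + offs[i, 2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || !mask[rr, cc]) { keep <- FALSE; break }
    }
    out[r, c] <- keep
  }
  out
}

# hole filling: mark background reachable from the border (4-connectivity),
# everything else becomes foreground
bf_fill_holes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  reach <- matrix(FALSE, nr, nc)
  stack <- list()
  for (r in seq_len(nr)) for (c in c(1L, nc))
    if (!mask[r, c] && !reach[r, c]) { reach[r, c] <- TRUE; stack[[length(stack)+1L]] <- c(r, c) }
  for (c in seq_len(nc)) for (r in c(1L, nr))
    if (!mask[r, c] && !reach[r, c]) { reach[r, c] <- TRUE; stack[[length(stack)+1L]] <- c(r, c) }
  while (length(stack)) {
    p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    for (d in list(c(-1,0),c(1,0),c(0,-1),c(0,1))) {
      rr <- p[1] + d[1]; cc <- p[2] + d[2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
          !mask[rr, cc] && !reach[rr, cc]) {
        reach[rr, cc] <- TRUE
        stack[[length(stack) + 1L]] <- c(rr, cc)
      }
    }
  }
  mask | !reach
}

bf_sieve <- function(labels, mode, threshold) {
  n <- max(labels)
  out <- matrix(0L, nrow(labels), ncol(labels))
  nxt <- 0L
  for (k in seq_len(n)) {
    a <- sum(labels == k)
    keep <- if (mode == "greater_than") a > threshold else a < threshold
    if (keep) { nxt <- nxt + 1L; out[labels == k] <- nxt }
  }
  out
}

# nearest-seed clump splitting: integer squared distances, ties to the
# lower seed label; components without seeds get fresh labels in raster
# order of their first pixel
bf_break_clumps <- function(mask, seeds, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  comp <- bf_label(mask, connectivity)
  seeded_comps <- sort(unique(comp[comp > 0 & seeds > 0]))
  labs <- sort(unique(seeds[seeds > 0]))
  seedpix <- lapply(labs, function(k) which(seeds == k, arr.ind = TRUE))
  vor <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || !(comp[r, c] %in% seeded_comps)) next
    bestd <- Inf; bestl <- 0L
    for (i in seq_along(labs)) {
      px <- seedpix[[i]]
      d <- min((px[, 1] - r)^2 + (px[, 2] - c)^2)
      if (d < bestd) { bestd <- d; bestl <- labs[i] }
    }
    vor[r, c] <- bestl
  }
  present <- sort(unique(vor[vor > 0]))
  out <- matrix(0L, nr, nc)
  for (i in seq_along(present)) out[vor == present[i]] <- i
  nxt <- length(present)
  for (k in setdiff(seq_len(max(comp, 0)), seeded_comps)) {
    nxt <- nxt + 1L
    out[comp == k] <- nxt
  }
  out
}

# all-pairs overlap census for the nucleation rule
bf_link_survivors <- function(nuclei, cells, fraction, denominator = "primary") {
  survivors <- integer(0)
  P <- 1e6; fP <- round(fraction * P)
  for (ci in seq_len(max(cells, 0))) {
    keep <- FALSE
    for (ni in seq_len(max(nuclei, 0))) {
      inter <- sum(nuclei == ni & cells == ci)
      denom <- if (denominator == "primary") sum(nuclei == ni) else sum(cells == ci)
      if (denom > 0 && inter * P >= fP * denom) { keep <- TRUE; break }
    }
    if (keep) survivors <- c(survivors, ci)
  }
  survivors
}

# small synthetic field shared by protocol-level tests (fast)
small_scene <- function(seed, nCells = 10, gfpFraction = 0.4, rfpFraction = 0,
                        snr = 10, clumpProbability = 0.2)
  sceneParams(height = 288, width = 288, nCells = nCells,
              gfpFraction = gfpFraction, rfpFraction = rfpFraction,
              clumpProbability = clumpProbability, snr = snr,
              postBase = 60, postSpacing = 60, rngSeed = seed)
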