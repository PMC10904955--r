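block_labels <- function(nr, nc, blocks) {
  lab <- matrix(0L, nr, nc)
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    lab[b$r, b$c] <- i
  }
  lab
}

test_that("mask subtraction is exact set difference", {
  a <- matrix(FALSE, 10, 10); a[1:10, 1:10] <- TRUE
  b <- matrix(FALSE, 10, 10); b[1:3, 1:10] <- TRUE
  expect_identical(sum(maskSubtract(a, b)), 70L)
  expect_identical(maskSubtract(a, matrix(FALSE, 10, 10)), a)
  expect_false(any(maskSubtract(b, a)))
  expect_error(maskSubtract(a, matrix(FALSE, 5, 5)), "share dimensions")
})

test_that("debris exclusion removes exactly the debris pixels", {
  cells <- matrix(FALSE, 10, 10); cells[2:9, 2:9] <- TRUE
  none <- matrix(0L, 10, 10)
  expect_identical(excludeDebris(cells, none), cells)
  debris <- matrix(0L, 10, 10); debris[1, 1] <- 1L
  expect_identical(excludeDebris(cells, debris), cells)  # disjoint
  debris2 <- matrix(0L, 10, 10); debris2[2:3, 2:4] <- 1L
  expect_identical(sum(excludeDebris(cells, debris2)), sum(cells) - 6L)
})

test_that("the 80% nucleation boundary is integer-exact", {
  # nucleus of 50 px, exactly 40 inside the cell -> retained (40/50 = 0.8)
  nuclei <- matrix(0L, 20, 20); nuclei[6:10, 6:15] <- 1L      # 5x10 = 50 px
  cells <- matrix(0L, 20, 20); cells[1:20, 8:20] <- 1L        # covers cols 8..15 of it
  inside <- sum(nuclei == 1L & cells == 1L)
  expect_identical(inside, 40L)
  w <- linkByOverlap(nuclei, cells, linkSpec(secondary = "cells", overlapFraction = 0.8))
  expect_identical(nObjects(w), 1L)
  expect_identical(unname(nucleusOf(w)["1"]), 1L)

  # 39 of 50 inside -> removed (0.78 < 0.8)
  cells39 <- matrix(0L, 20, 20); cells39[1:20, 8:20] <- 1L; cells39[6, 15] <- 0L
  expect_identical(sum(nuclei == 1L & cells39 == 1L), 39L)
  w39 <- linkByOverlap(nuclei, cells39, linkSpec(secondary = "cells", overlapFraction = 0.8))
  expect_identical(nObjects(w39), 0L)
})

test_that("overlap linking agrees with the all-pairs census on random label maps", {
  withr::local_seed(19)
  for (i in 1:60) {
    nr <- sample(8:24, 1); nc <- sample(8:24, 1)
    nuclei <- labelComponents(rand_mask(nr, nc, runif(1, 0.2, 0.5)), 8)
    cells <- labelComponents(rand_mask(nr, nc, runif(1, 0.3, 0.6)), 8)
    f <- sample(c(0.25, 0.5, 0.8, 1), 1)
    denom <- sample(c("primary", "secondary"), 1)
    w <- linkByOverlap(nuclei, cells,
                       linkSpec(secondary = "cells", overlapFraction = f,
                                denominator = denom))
    oracle <- bf_link_survivors(nuclei, cells, f, denom)
    got <- sort(unique(cells[cellLabels(w) > 0L]))
    expect_identical(got, oracle)
    # relabelling is contiguous and order-preserving
    expect_true(isLabelMap(cellLabels(w)))
  }
})

test_that("linking is monotone in the overlap fraction", {
  withr::local_seed(43)
  for (i in 1:20) {
    nuclei <- labelComponents(rand_mask(16, 16, 0.3), 8)
    cells <- labelComponents(rand_mask(16, 16, 0.5), 8)
    hi <- cells[cellLabels(linkByOverlap(nuclei, cells,
            linkSpec(secondary = "c", overlapFraction = 0.9))) > 0L]
    lo <- cells[cellLabels(linkByOverlap(nuclei, cells,
            linkSpec(secondary = "c", overlapFraction = 0.3))) > 0L]
    expect_true(all(unique(hi) %in% unique(lo)))
  }
})

test_that("cells without any nucleus pixel are always removed", {
  withr::local_seed(47)
  for (i in 1:20) {
    nuclei <- labelComponents(rand_mask(16, 16, 0.2), 8)
    cells <- labelComponents(rand_mask(16, 16, 0.5), 8)
    w <- linkByOverlap(nuclei, cells,
                       linkSpec(secondary = "c", overlapFraction = 0.05))
    surv <- sort(unique(cells[cellLabels(w) > 0L]))
    for (ci in surv) expect_gt(sum(cells == ci & nuclei > 0L), 0L)
  }
})

test_that("every surviving object satisfies the configured rule", {
  withr::local_seed(53)
  nuclei <- labelComponents(rand_mask(24, 24, 0.3), 8)
  cells <- labelComponents(rand_mask(24, 24, 0.5), 8)
  f <- 0.6
  w <- linkByOverlap(nuclei, cells, linkSpec(secondary = "c", overlapFraction = f))
  lab <- cellLabels(w)
  nuc <- nucleusOf(w)
  for (k in seq_len(nObjects(w))) {
    ni <- nuc[[as.character(k)]]
    inter <- sum(nuclei == ni & lab == k)
    expect_gte(inter / sum(nuclei == ni), f - 1e-12)
  }
})
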