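test_that("erosion matches the analytic case and the per-pixel oracle", {
  m <- matrix(FALSE, 7, 7); m[2:6, 2:6] <- TRUE
  er <- erodeMask(m, structuringElement("square", 3))
  expect_identical(sum(er), 9L)
  expect_true(all(which(er, arr.ind = TRUE) >= 3 & which(er, arr.ind = TRUE) <= 5))

  expect_false(any(erodeMask(matrix(FALSE, 6, 6), structuringElement("square", 3))))

  withr::local_seed(12)
  for (i in 1:60) {
    mask <- rand_mask(sample(5:20, 1), sample(5:20, 1), runif(1, 0.4, 0.8))
    se <- structuringElement(sample(c("disc", "square"), 1), sample(c(2, 3, 5), 1))
    got <- erodeMask(mask, se)
    expect_identical(got, bf_erode(mask, chipcyte:::.seFootprint(se)))
    expect_true(all(mask[got]))  # anti-extensive
  }
})

test_that("hole filling closes enclosed background and leaves border bays", {
  ring <- matrix(FALSE, 5, 5)
  ring[1, ] <- ring[5, ] <- ring[, 1] <- ring[, 5] <- TRUE
  expect_identical(sum(fillHoles(ring)), 25L)

  bay <- matrix(FALSE, 5, 7)
  bay[2:4, 2:6] <- TRUE
  bay[2:3, 4] <- FALSE  # notch connected to the top border through (1, 4)
  expect_identical(fillHoles(bay), bay)
})

test_that("hole filling is extensive and idempotent on random masks", {
  withr::local_seed(23)
  for (i in 1:100) {
    mask <- rand_mask(sample(4:24, 1), sample(4:24, 1), runif(1, 0.3, 0.7))
    filled <- fillHoles(mask)
    expect_true(all(mask[filled] | !mask[filled]))  # shape preserved
    expect_true(all(filled[mask]))                  # extensive
    expect_identical(fillHoles(filled), filled)     # idempotent
    expect_identical(filled, bf_fill_holes(mask))   # oracle
  }
})

test_that("sieve retains by strict inequality and preserves survivor pixels", {
  lab <- matrix(0L, 12, 24)
  lab[2:4, 2:5] <- 1L    # area 12
  lab[6:9, 2:6] <- 2L    # area 20
  lab[2:10, 10:14] <- 3L # area 45
  gt <- sieveObjects(lab, sievePredicate("greater_than", 20))
  expect_identical(max(gt), 1L)
  expect_identical(sum(gt == 1L), 45L)
  expect_identical(which(gt == 1L), which(lab == 3L))  # pixel set untouched
  lt <- sieveObjects(lab, sievePredicate("less_than", 20))
  expect_identical(max(lt), 1L)
  expect_identical(sum(lt == 1L), 12L)
  empty <- matrix(0L, 4, 4)
  expect_identical(sieveObjects(empty, sievePredicate("greater_than", 5)), empty)
})

test_that("clump breaking splits touching discs at the perpendicular bisector", {
  nr <- 40; nc <- 40
  c1 <- c(20, 14); c2 <- c(20, 26)  # centres 12 px apart on the x axis
  d1 <- outer((1:nr - c1[1])^2, (1:nc - c1[2])^2, "+")
  d2 <- outer((1:nr - c2[1])^2, (1:nc - c2[2])^2, "+")
  mask <- d1 <= 100 | d2 <= 100
  seeds <- matrix(0L, nr, nc); seeds[c1[1], c1[2]] <- 1L; seeds[c2[1], c2[2]] <- 2L
  lab <- breakClumps(mask, seeds)
  expect_identical(max(lab), 2L)
  expect_identical(sum(lab > 0L), sum(mask))  # pixel conserving
  # exhaustive per-pixel check: boundary at the bisector column +/- 1 px
  bis <- (c1[2] + c2[2]) / 2
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (lab[r, c] == 1L) expect_lte(c, bis + 1)
    if (lab[r, c] == 2L) expect_gte(c, bis - 1)
  }
})

test_that("clump breaking with one embedded seed returns the mask unchanged", {
  mask <- matrix(FALSE, 15, 15); mask[4:12, 4:12] <- TRUE
  seeds <- matrix(0L, 15, 15); seeds[8, 8] <- 1L
  lab <- breakClumps(mask, seeds)
  expect_identical(lab > 0L, mask)
  expect_identical(max(lab), 1L)
})

test_that("clump breaking equals the exhaustive nearest-seed oracle", {
  withr::local_seed(31)
  for (i in 1:60) {
    nr <- sample(8:32, 1); nc <- sample(8:32, 1)
    mask <- rand_mask(nr, nc, runif(1, 0.4, 0.8))
    seeds <- matrix(0L, nr, nc)
    fg <- which(mask)
    if (length(fg) >= 3) {
      pick <- sample(fg, min(3, length(fg)))
      seeds[pick] <- seq_along(pick)
    }
    got <- breakClumps(mask, seeds)
    expect_identical(got, bf_break_clumps(mask, seeds))
    expect_identical(sum(got > 0L), sum(mask))
  }
})

test_that("every assigned pixel is at least as close to its own seed", {
  withr::local_seed(37)
  for (i in 1:20) {
    mask <- rand_mask(20, 20, 0.7)
    seeds <- matrix(0L, 20, 20)
    fg <- which(mask)
    pick <- sample(fg, min(4, length(fg)))
    seeds[pick] <- seq_along(pick)
    lab <- breakClumps(mask, seeds)
    coords <- lapply(seq_along(pick), function(k) which(seeds == k, arr.ind = TRUE))
    for (p in which(lab > 0L & lab <= length(pick))) {
      r <- (p - 1) %% 20 + 1; c <- (p - 1) %/% 20 + 1
      dists <- vapply(coords, function(px) min((px[, 1] - r)^2 + (px[, 2] - c)^2),
                      numeric(1))
      expect_lte(dists[lab[p]], min(dists))
    }
  }
})

test_that("seedless components receive fresh labels containing no seed", {
  mask <- matrix(FALSE, 20, 20)
  mask[2:6, 2:6] <- TRUE    # will hold the seed
  mask[12:16, 12:16] <- TRUE  # seedless island
  seeds <- matrix(0L, 20, 20); seeds[4, 4] <- 1L
  lab <- breakClumps(mask, seeds)
  expect_identical(max(lab), 2L)
  expect_true(all(seeds[lab == 2L] == 0L))
  expect_identical(sum(lab > 0L), sum(mask))
})

test_that("centroid-distance clump breaking also matches a brute-force rule", {
  mask <- matrix(TRUE, 20, 21)
  seeds <- matrix(0L, 20, 21)
  seeds[10, 5] <- 1L; seeds[10, 17] <- 2L
  lab <- breakClumps(mask, seeds, distanceTo = "centroid")
  expect_identical(max(lab), 2L)
  expect_true(all(lab[, 1:11] == 1L))  # tie column 11 goes to the lower label
  expect_true(all(lab[, 12:21] == 2L))
})

test_that("per-label hole filling fills only within each object", {
  lab <- matrix(0L, 10, 10)
  lab[2:6, 2:6] <- 1L; lab[3:5, 3:5] <- 0L  # object 1 with a hole
  lab[8:9, 2:9] <- 2L
  out <- fillHolesLabels(lab)
  expect_true(all(out[3:5, 3:5] == 1L))
  expect_identical(out[8:9, 2:9], lab[8:9, 2:9])
})
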