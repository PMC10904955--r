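gaussian_blob <- function(nr, nc, cy, cx, sigma, peak, bg = 100) {
  d2 <- outer((seq_len(nr) - cy)^2, (seq_len(nc) - cx)^2, "+")
  round(bg + peak * exp(-d2 / (2 * sigma^2)))
}

test_that("object segmentation finds nothing on a contrast-free plane", {
  expect_false(any(segmentObjects(matrix(500, 64, 64), objectSegParams(15, 50))))
  expect_false(any(segmentObjects(matrix(0, 64, 64), objectSegParams(15, 50))))
})

test_that("object segmentation isolates a single bright blob", {
  pl <- gaussian_blob(64, 64, 32, 32, sigma = 4, peak = 900, bg = 100)
  m <- segmentObjects(pl, objectSegParams(15, 50))
  lab <- bf_label(m, 8)
  expect_identical(max(lab), 1L)
  expect_true(m[32, 32])
})

test_that("object segmentation recovers well-separated blobs and stays silent off them", {
  # 20 blobs in three quadrants of a 256x256 plane; lower-right kept empty
  centres <- rbind(expand.grid(r = c(30, 75, 120), c = c(30, 75, 120)),
                   expand.grid(r = c(30, 75, 120), c = c(170, 215)),
                   expand.grid(r = c(170, 215), c = c(30, 70, 110)))[1:20, ]
  pl <- matrix(100, 256, 256)
  for (i in seq_len(nrow(centres)))
    pl <- pl + gaussian_blob(256, 256, centres$r[i], centres$c[i], 5, 1200, bg = 0)
  m <- segmentObjects(pl, objectSegParams(15, 50))
  covered <- sum(vapply(seq_len(nrow(centres)),
                        function(i) m[centres$r[i], centres$c[i]], logical(1)))
  expect_gte(covered, 19L)
  expect_false(any(m[150:256, 150:256]))
})

test_that("object segmentation is invariant to a constant intensity offset", {
  pl <- gaussian_blob(72, 72, 30, 40, 4, 900, bg = 120)
  m1 <- segmentObjects(pl, objectSegParams(15, 50))
  m2 <- segmentObjects(pl + 500, objectSegParams(15, 50))
  expect_identical(m1, m2)
})

test_that("object segmentation rejects kernels larger than the plane", {
  expect_error(segmentObjects(matrix(0, 10, 10), objectSegParams(15, 50)),
               "exceeds image dimensions")
})

test_that("intensity segmentation is an inclusive per-pixel range test", {
  pl <- matrix(c(0, 1, 65535), 1, 3)
  m <- segmentIntensity(pl, intensityRange(1, 65535))
  expect_identical(as.vector(m), c(FALSE, TRUE, TRUE))
  expect_true(all(segmentIntensity(pl, intensityRange(0, 65535))))

  withr::local_seed(11)
  for (i in 1:20) {
    plane <- matrix(sample(0:65535, 24 * 24, TRUE), 24, 24)
    a <- sample(0:60000, 1); b <- a + sample(0:5000, 1)
    m <- segmentIntensity(plane, intensityRange(a, b))
    expect_identical(sum(m), sum(plane >= a & plane <= b))
  }
})

test_that("intensity segmentation is monotone in the range", {
  withr::local_seed(5)
  plane <- matrix(sample(0:1000, 32 * 32, TRUE), 32, 32)
  inner <- segmentIntensity(plane, intensityRange(200, 600))
  outer_ <- segmentIntensity(plane, intensityRange(100, 900))
  expect_true(all(outer_[inner]))
})

test_that("connected components match the flood-fill oracle", {
  m <- matrix(FALSE, 4, 4); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_identical(max(labelComponents(m, 4)), 2L)
  expect_identical(max(labelComponents(m, 8)), 1L)
  expect_identical(max(labelComponents(matrix(FALSE, 5, 5), 8)), 0L)

  withr::local_seed(99)
  for (i in 1:200) {
    mask <- rand_mask(sample(4:32, 1), sample(4:32, 1), runif(1, 0.2, 0.6))
    conn <- sample(c(4L, 8L), 1)
    expect_identical(labelComponents(mask, conn), bf_label(mask, conn))
  }
})

test_that("label maps partition their mask", {
  withr::local_seed(3)
  mask <- rand_mask(40, 40, 0.4)
  lab <- labelComponents(mask, 8)
  expect_identical(lab > 0L, mask)
  expect_true(isLabelMap(lab))
})

disc_plane <- function(nr, nc, centres, r, value, bg = 500) {
  pl <- matrix(bg, nr, nc)
  for (i in seq_len(nrow(centres))) {
    d2 <- outer((seq_len(nr) - centres[i, 1])^2, (seq_len(nc) - centres[i, 2])^2, "+")
    pl[d2 <= r[i]^2] <- value
  }
  pl
}

point_seeds <- function(nr, nc, centres) {
  s <- matrix(0L, nr, nc)
  for (i in seq_len(nrow(centres))) s[centres[i, 1], centres[i, 2]] <- i
  s
}

test_that("nuclear segmentation grows one object per seed and applies the area cut", {
  centres <- rbind(c(40, 40), c(40, 100))
  pl <- disc_plane(140, 140, centres, r = c(18, 18), value = 1500)
  seeds <- point_seeds(140, 140, centres)
  lab <- segmentNuclei(pl, seeds, nuclearSegParams(600, 15))
  expect_identical(max(lab), 2L)
  areas <- tabulate(lab[lab > 0])
  expect_true(all(abs(areas - pi * 18^2) / (pi * 18^2) <= 0.1))

  # a dim disc below the minimum target area is discarded
  pl2 <- disc_plane(80, 80, rbind(c(40, 40)), r = 11.2, value = 1500)  # ~394 px
  lab2 <- segmentNuclei(pl2, point_seeds(80, 80, rbind(c(40, 40))),
                        nuclearSegParams(600, 15))
  expect_identical(max(lab2), 0L)

  # no seeds -> no nuclei
  expect_identical(max(segmentNuclei(pl, matrix(0L, 140, 140),
                                     nuclearSegParams(600, 15))), 0L)
  expect_error(segmentNuclei(pl, matrix(0L, 3, 3)), "not aligned")
})

test_that("nuclei are disjoint and each contains a pixel of its seed", {
  f <- generateField(small_scene(21))
  seeds <- sieveObjects(
    labelComponents(erodeMask(segmentObjects(f$image@planes$nuclear),
                              structuringElement("disc", 16))),
    sievePredicate("greater_than", 20))
  lab <- segmentNuclei(f$image@planes$nuclear, seeds, nuclearSegParams(600, 15))
  expect_gt(max(lab), 0L)
  for (k in seq_len(max(lab))) {
    sel <- lab == k
    expect_true(any(seeds[sel] > 0L))
  }
  # disjointness is inherent to a label map; overlap would be double labels
  expect_true(isLabelMap(lab))
})

test_that("Otsu-based automatic range splits a bimodal plane", {
  withr::local_seed(8)
  pl <- matrix(round(c(rnorm(700, 500, 30), rnorm(300, 5000, 100))), 25, 40)
  pl[pl < 0] <- 0
  rng <- autoIntensityRange(pl)
  # the threshold must separate the two intensity modes
  lo <- pl[pl < 2000]; hi <- pl[pl >= 2000]
  expect_gte(mean(lo < rng@minimum), 0.99)
  expect_true(all(hi >= rng@minimum))
  expect_identical(rng@maximum, 65535)
})
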