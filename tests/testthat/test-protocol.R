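test_that("config validation catches structural mistakes", {
  cfg <- protocol1Config()
  expect_s4_class(cfg, "ProtocolConfig")
  # undefined reference
  bad <- cfg
  bad@steps[[2]]$params$seeds <- "nonexistent"
  expect_error(validObject(bad), "seeds target")
  # two nuclear targets
  bad2 <- cfg
  bad2@steps[[6]] <- bad2@steps[[2]]
  bad2@steps[[6]]$name <- "nuclei2"
  expect_error(validObject(bad2), "exactly one nuclear")
  # link to a missing target
  bad3 <- cfg
  bad3@links[[1]]$secondary <- "missing"
  expect_error(validObject(bad3), "undefined target")
})

test_that("protocol configs survive the YAML round trip", {
  for (cfg in list(protocol1Config(), protocol2Config())) {
    p <- withr::local_tempfile(fileext = ".yaml")
    writeProtocolConfig(cfg, p)
    back <- readProtocolConfig(p)
    expect_identical(back@name, cfg@name)
    expect_identical(back@channels, cfg@channels)
    expect_identical(length(back@steps), length(cfg@steps))
    expect_identical(back@partitionCheck, cfg@partitionCheck)
    # and the round-tripped config runs
    expect_s4_class(back, "ProtocolConfig")
    expect_null(chipcyte:::.validateConfig(back))
  }
})

test_that("the shipped preset files match the programmatic presets", {
  for (nm in c("protocol1", "protocol2")) {
    p <- system.file("protocols", paste0(nm, ".yaml"), package = "chipcyte")
    expect_true(nzchar(p))
    cfg <- readProtocolConfig(p)
    ref <- if (nm == "protocol1") protocol1Config() else protocol2Config()
    expect_identical(cfg@steps, ref@steps)
    expect_identical(cfg@links, ref@links)
  }
})

test_that("missing channel roles are a configuration error", {
  f <- generateField(small_scene(2))
  img <- f$image
  img@planes$gfp <- NULL
  expect_error(runProtocol1(img), "lacks required channel")
})

test_that("protocol 1 classifies a small co-culture field", {
  f <- generateField(small_scene(14, nCells = 10, gfpFraction = 0.4))
  res <- runProtocol1(f$image, fieldId = "t1")
  nGfpTruth <- sum(truthClasses(f$truth) == "gfp")
  wp <- wholeCells(res, "gfp_positive"); wn <- wholeCells(res, "gfp_negative")
  expect_lte(abs(nObjects(wp) - nGfpTruth), 1L)
  expect_lte(abs(nObjects(wn) - (10 - nGfpTruth)), 2L)
  # measurement table covers both classes with consistent totals
  s <- fieldSummary(res)
  expect_identical(sum(s$perField$count), nObjects(wp) + nObjects(wn))
  obj <- measurements(res)
  expect_identical(nrow(obj), nObjects(wp) + nObjects(wn))
  expect_true(all(obj$field_id == "t1"))
  # every target named in the config is present in the result
  expect_setequal(names(res@targets),
                  vapply(protocol1Config()@steps, `[[`, "", "name"))
})

test_that("protocol 2 separates GFP and RFP populations", {
  f <- generateField(small_scene(15, nCells = 8, gfpFraction = 0.5,
                                 rfpFraction = 0.5))
  res <- runProtocol2(f$image)
  expect_lte(abs(nObjects(wholeCells(res, "gfp")) -
                 sum(truthClasses(f$truth) == "gfp")), 1L)
  expect_lte(abs(nObjects(wholeCells(res, "rfp")) -
                 sum(truthClasses(f$truth) == "rfp")), 1L)
})

test_that("zeroed channels give zero cells without crashing", {
  f <- generateField(small_scene(16, nCells = 6))
  imgNoGfp <- f$image
  imgNoGfp@planes$gfp[] <- 0L
  res <- runProtocol1(imgNoGfp)
  expect_identical(nObjects(wholeCells(res, "gfp_positive")), 0L)
  expect_gt(nObjects(wholeCells(res, "gfp_negative")), 0L)

  imgNoNuc <- f$image
  imgNoNuc@planes$nuclear[] <- 0L
  res2 <- runProtocol1(imgNoNuc)
  expect_identical(nObjects(wholeCells(res2, "gfp_positive")), 0L)
  expect_identical(nObjects(wholeCells(res2, "gfp_negative")), 0L)
  expect_identical(nrow(measurements(res2)), 0L)

  imgNoRfp <- f$image
  imgNoRfp@planes$rfp[] <- 0L
  res3 <- runProtocol2(imgNoRfp)
  expect_identical(nObjects(wholeCells(res3, "rfp")), 0L)
})

test_that("repeated runs are bit-identical, including the CSV output", {
  f <- generateField(small_scene(17))
  r1 <- runProtocol1(f$image)
  r2 <- runProtocol1(f$image)
  expect_identical(r1@targets, r2@targets)
  expect_identical(lapply(r1@wholeCells, cellLabels),
                   lapply(r2@wholeCells, cellLabels))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- writeMeasurements(measurements(r1), d1)
  p2 <- writeMeasurements(measurements(r2), d2)
  for (i in seq_along(p1))
    expect_identical(readLines(p1[i]), readLines(p2[i]))
})

test_that("debris exclusion policy is wired through the engine", {
  f <- generateField(small_scene(18, nCells = 6))
  res <- runProtocol(f$image, protocol1Config(debrisPolicy = "exclude"))
  expect_true("debris" %in% names(res@targets))
  # with exclusion enabled, cell pixels never coincide with debris objects
  expect_false(any(targetMask(res, "cells") & targetLabels(res, "debris") > 0L))
})
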