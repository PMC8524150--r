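test_that("synthetic sections are deterministic with exact ground truth", {
  blank <- generateSyntheticSection(0, seed = 1)
  expect_equal(nrow(blank@ground_truth), 0)
  band <- testBand()
  expect_equal(nrow(countParticles(blank, band)), 0)

  a <- generateSyntheticSection(25, seed = 42)
  b <- generateSyntheticSection(25, seed = 42)
  expect_identical(a@pixels, b@pixels)
  expect_equal(a@ground_truth, b@ground_truth)
  expect_false(identical(a@pixels, generateSyntheticSection(25, seed = 43)@pixels))
  # all planted cells inside the ROI
  expect_true(all(stopchange:::pointInPolygon(a@ground_truth$x,
                                              a@ground_truth$y, a@roi)))
  expect_error(generateSyntheticSection(10000, width = 64, height = 64,
                                        seed = 1, max_attempts = 5000),
               "non-overlapping")
})

test_that("threshold calibration brackets the exemplar intensities", {
  b <- calibrateThresholds(exemplar_peaks = c(60, 200))
  expect_equal(c(b@lower, b@upper), c(60, 200))
  b1 <- calibrateThresholds(exemplar_peaks = 120)
  expect_equal(c(b1@lower, b1@upper), c(120, 120))
  expect_error(calibrateThresholds(), "no exemplar")

  secs <- lapply(1:3, function(s) generateSyntheticSection(30, seed = s))
  band <- calibrateThresholds(secs)
  peaks <- unlist(lapply(secs, function(s) s@ground_truth$peak))
  expect_gte(mean(peaks >= band@lower & peaks <= band@upper), 0.95)
})

test_that("particle filters apply the strict size and roundness cutoffs", {
  band <- testBand()
  # one disc of radius 3 (area 29 px, roundness ~ 1) -> kept
  m <- stampDisc(matrix(FALSE, 64, 64), 20.5, 20.5, 3)
  p <- countParticles(maskImage(m), band)
  expect_equal(nrow(p), 1)
  expect_equal(p$area_px, 29)
  expect_gt(p$roundness, 0.9)
  # a 10-px blob fails the >15 px size filter
  m10 <- matrix(FALSE, 64, 64); m10[10:11, 10:14] <- TRUE
  expect_equal(nrow(countParticles(maskImage(m10), band)), 0)
  # a 1 x 40 line (roundness ~ 0.03) fails the roundness filter
  line <- matrix(FALSE, 64, 64); line[30, 11:50] <- TRUE
  expect_equal(nrow(countParticles(maskImage(line), band)), 0)
  # exactly 16 px in a 4x4 square passes >15 and is round
  sq <- matrix(FALSE, 64, 64); sq[5:8, 5:8] <- TRUE
  expect_equal(nrow(countParticles(maskImage(sq), band)), 1)
})

test_that("out-of-band intensities are not detected", {
  m <- stampDisc(matrix(FALSE, 64, 64), 32, 32, 4)
  img <- sectionImage(255 - ifelse(m, 100, 0))  # stain 100
  expect_equal(nrow(countParticles(img, testBand())), 0)     # below band
  expect_equal(nrow(countParticles(img,
    calibrateThresholds(exemplar_peaks = c(50, 150)))), 1)   # inside band
})

test_that("counting matches the flood-fill oracle on random images", {
  band <- testBand()
  set.seed(99)
  for (i in 1:40) {
    m <- matrix(FALSE, 64, 64)
    for (k in seq_len(sample(1:6, 1)))
      m <- stampDisc(m, runif(1, 5, 59), runif(1, 5, 59), runif(1, 1, 5))
    m <- m | (matrix(runif(64 * 64), 64) < 0.02)  # speckle noise
    got <- countParticles(maskImage(m), band)
    want <- oracleParticles(m)
    expect_equal(nrow(got), nrow(want))
    expect_equal(sort(got$area_px), sort(want$area))
    expect_equal(sort(got$roundness), sort(want$roundness), tolerance = 1e-9)
  }
})

test_that("counts are invariant to ROI-preserving translation", {
  m <- stampDisc(matrix(FALSE, 64, 64), 20, 24, 3.5)
  m <- stampDisc(m, 40, 40, 2.8)
  shift <- 7L
  m2 <- matrix(FALSE, 64, 64)
  m2[(1 + shift):64, (1 + shift):64] <- m[1:(64 - shift), 1:(64 - shift)]
  band <- testBand()
  p1 <- countParticles(maskImage(m), band)
  p2 <- countParticles(maskImage(m2), band)
  expect_equal(nrow(p1), nrow(p2))
  expect_equal(sort(p1$area_px), sort(p2$area_px))
  expect_equal(sort(p1$centroid_x) + shift, sort(p2$centroid_x))
})

test_that("well-separated planted cells are recovered without false positives", {
  hits <- 0; planted <- 0; extra <- 0
  for (s in 1:4) {
    sec <- generateSyntheticSection(40, seed = s)
    band <- calibrateThresholds(list(sec))
    p <- countParticles(sec, band)
    planted <- planted + nrow(sec@ground_truth)
    hits <- hits + nrow(p)
    extra <- extra + max(nrow(p) - nrow(sec@ground_truth), 0)
  }
  expect_gte(hits / planted, 0.95)
  expect_equal(extra, 0)
})

test_that("density standardisation scales as pixel_size^-2", {
  expect_equal(densityPerMm2(50, 250000, 0.001), 200)
  expect_equal(densityPerMm2(0, 250000, 0.001), 0)
  d1 <- densityPerMm2(37, 10000, 0.002)
  d2 <- densityPerMm2(37, 10000, 0.004)
  expect_equal(d2, d1 / 4)
  expect_error(densityPerMm2(5, 0, 0.001), "roi_area_px")
})

test_that("slice and hemisphere aggregation takes nested means", {
  d <- expand.grid(slice = 1:3, hemisphere = c("left", "right"),
                   subject_id = "P1", area_label = "NIML",
                   stringsAsFactors = FALSE)
  d$cells_per_mm2 <- c(90, 100, 110, 290, 300, 310)  # hemis average 100, 300
  agg <- aggregateSubject(d)
  expect_equal(agg$cells_per_mm2, 200)
  expect_equal(agg$n_slices_averaged, 6)
  expect_true(agg$complete)

  d$cells_per_mm2 <- rep(42, 6)
  expect_equal(aggregateSubject(d)$cells_per_mm2, 42)

  # missing slice: warn, aggregate what is there, flag incomplete
  expect_warning(agg2 <- aggregateSubject(d[-1, ]), "expected 3")
  expect_false(agg2$complete)

  # per-hemisphere output when pooling is off
  byh <- aggregateSubject(d, pool_hemispheres = FALSE)
  expect_equal(nrow(byh), 2)
  expect_setequal(byh$hemisphere, c("left", "right"))
})

test_that("nested aggregation equals the hand-computed value", {
  d <- data.frame(subject_id = "P1", area_label = "CPi",
                  hemisphere = rep(c("left", "right"), each = 2),
                  slice = c(1, 2, 1, 2),
                  cells_per_mm2 = c(811, 845, 790, 902))
  expect_equal(aggregateSubject(d)$cells_per_mm2,
               mean(c(mean(c(811, 845)), mean(c(790, 902)))))
})

test_that("section images round-trip through PNG", {
  skip_if_not_installed("png")
  sec <- generateSyntheticSection(10, width = 64, height = 64, seed = 2)
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(sec@pixels / 255, path)
  back <- readSectionImage(path, pixel_size = sec@pixel_size, roi = sec@roi)
  expect_equal(back@pixels, sec@pixels)
})
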