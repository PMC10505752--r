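test_that("the printed band boundaries classify exactly", {
  img <- IntensityImage(matrix(c(70L, 71L, 100L, 101L, 130L, 131L,
                                 175L, 176L), 1))
  expect_equal(as.vector(classifyLevels(img)),
               c(4, 3, 3, 2, 2, 1, 1, 0))
})

test_that("bands are disjoint and cover [0, 255]; every value gets one level", {
  th <- LevelThresholds()
  covered <- integer(256)
  for (l in 0:4) {
    idx <- (th@lower[[as.character(l)]]:th@upper[[as.character(l)]]) + 1L
    covered[idx] <- covered[idx] + 1L
  }
  expect_true(all(covered == 1L))
  # full-range image: per-level counts equal brute-force interval membership
  img <- IntensityImage(matrix(0:255, 16))
  lv <- classifyLevels(img)
  v <- intensityValues(img)
  for (l in 0:4)
    expect_equal(sum(lv == l),
                 sum(v >= th@lower[[as.character(l)]] &
                       v <= th@upper[[as.character(l)]]))
  expect_error(LevelThresholds(level1 = c(120L, 175L)), "overlap")
  expect_error(LevelThresholds(background = c(180L, 255L)), "cover")
})

test_that("an all-background image classifies entirely to level 0", {
  lv <- classifyLevels(IntensityImage(matrix(255L, 20, 20)))
  expect_true(all(lv == 0L))
})

test_that("deconvolution is monotone in DAB density and fixes white at 255", {
  white <- array(255, dim = c(1, 1, 3))
  expect_equal(as.vector(intensityValues(computeIntensityImage(white))), 255)
  # pixels constructed at increasing DAB optical density must get
  # strictly decreasing values (direct OD construction as the oracle)
  dab <- hdabVectors()["dab", ]
  d <- c(0.05, 0.2, 0.5, 1.0, 1.5)
  px <- array(0, dim = c(1, length(d), 3))
  for (i in seq_along(d))
    px[1, i, ] <- round(255 * 10^(-d[i] * dab))
  v <- as.vector(intensityValues(computeIntensityImage(px)))
  expect_true(all(diff(v) < 0))
})

test_that("pass-through mode returns synthetic intensities unchanged", {
  out <- generateIHCImage(SyntheticImageSpec(30, 30, seed = 6))
  pt <- computeIntensityImage(intensityValues(out$intensity),
                              method = "passthrough")
  expect_identical(intensityValues(pt), intensityValues(out$intensity))
  expect_error(computeIntensityImage(matrix(1, 2, 2)), "RGB")
})

test_that("RGB rendering and unmixing agree on level classification", {
  out <- generateIHCImage(SyntheticImageSpec(
    60, 60, levelFractions = rep(0.12, 5), seed = 21))
  lvDirect <- classifyLevels(out$intensity)
  lvRGB <- classifyLevels(computeIntensityImage(out$rgb))
  expect_identical(lvDirect, lvRGB)
})

test_that("artifact detection follows the three rules", {
  clean <- generateIHCImage(SyntheticImageSpec(30, 30, seed = 9))$rgb
  expect_false(any(detectArtifacts(clean)))
  white <- array(255, dim = c(5, 5, 3))
  expect_true(all(detectArtifacts(white)))
  black <- array(0, dim = c(5, 5, 3))
  expect_true(all(detectArtifacts(black)))
  out <- generateIHCImage(SyntheticImageSpec(
    100, 100, levelFractions = rep(0.1, 5), artifactFraction = 0.1,
    seed = 13))
  det <- detectArtifacts(out$rgb)
  gtArea <- out$groundTruth$artifactArea
  expect_lt(abs(sum(det) - gtArea) / gtArea, 0.01)
})

test_that("measureROI reproduces the hand-worked normalization example", {
  vals <- matrix(200L, 100, 100)
  vals[seq_len(500)] <- 60L
  img <- IntensityImage(vals, pixelSize = 1)
  roi <- RegionOfInterest(matrix(TRUE, 100, 100))
  q <- measureROI(img, roi)
  expect_equal(unname(levelAreas(q)[["4"]]), 500)
  expect_equal(totalPositiveArea(q), 500)
  expect_equal(roiArea(q), 10000)
  expect_equal(unname(normalizedAreas(q)[["total"]]), 118500)
})

test_that("mean intensity is the plain mean and responds to lowered pixels", {
  img <- IntensityImage(matrix(140L, 10, 10))
  roi <- RegionOfInterest(matrix(TRUE, 10, 10))
  expect_equal(meanIntensity(measureROI(img, roi)), 140)
  v2 <- intensityValues(img); v2[1] <- 20L
  expect_lt(meanIntensity(measureROI(IntensityImage(v2), roi)), 140)
})

test_that("area conservation and artifact exclusion hold exactly", {
  out <- generateIHCImage(SyntheticImageSpec(
    80, 80, pixelSizeUm = 0.5, levelFractions = rep(0.1, 5),
    artifactFraction = 0.15, noiseSd = 4, seed = 17))
  q <- measureROI(out$intensity, out$roi, artifactMask = out$artifactMask)
  expect_equal(sum(levelAreas(q)) + artifactArea(q), roiArea(q))
  expect_equal(artifactArea(q), out$groundTruth$artifactArea)
  # degenerate ROI: everything artifact
  allArt <- matrix(TRUE, 80, 80)
  expect_error(measureROI(out$intensity, out$roi, artifactMask = allArt),
               "degenerate")
})

test_that("normalized areas are invariant under replication of the ROI", {
  vals <- matrix(c(rep(60L, 300), rep(150L, 700)), 50, 20)
  img1 <- IntensityImage(vals)
  q1 <- measureROI(img1, RegionOfInterest(matrix(TRUE, 50, 20)))
  img2 <- IntensityImage(cbind(vals, vals))
  q2 <- measureROI(img2, RegionOfInterest(matrix(TRUE, 50, 40)))
  expect_equal(normalizedAreas(q1), normalizedAreas(q2))
})

test_that("noiseless recovery is exact; noise_sd 5 keeps total within 2%", {
  for (seed in c(3, 19)) {
    clean <- generateIHCImage(SyntheticImageSpec(
      120, 120, levelFractions = c(0.2, 0.1, 0.1, 0.1, 0.1),
      noiseSd = 0, seed = seed))
    q <- measureROI(clean$intensity, clean$roi)
    expect_equal(levelAreas(q), clean$groundTruth$levelAreas)
    noisy <- generateIHCImage(SyntheticImageSpec(
      120, 120, levelFractions = c(0.2, 0.1, 0.1, 0.1, 0.1),
      noiseSd = 5, seed = seed))
    qn <- measureROI(noisy$intensity, noisy$roi)
    gtTotal <- noisy$groundTruth$totalPositiveArea
    expect_lt(abs(totalPositiveArea(qn) - gtTotal) / gtTotal, 0.02)
  }
})

test_that("raising DAB strength of a pixel never lowers its level", {
  v <- sort(sample(0:255, 60))
  lv <- as.vector(classifyLevels(IntensityImage(matrix(v, 1))))
  # v ascending = staining weakening, so levels must be non-increasing
  expect_true(all(diff(lv) <= 0))
})

test_that("positive-pixel MI mode restricts the average to stained pixels", {
  vals <- matrix(c(rep(60L, 50), rep(200L, 50)), 10, 10)
  img <- IntensityImage(vals)
  roi <- RegionOfInterest(matrix(TRUE, 10, 10))
  expect_equal(meanIntensity(measureROI(img, roi)), 130)
  expect_equal(meanIntensity(measureROI(img, roi, miPixels = "positive")), 60)
})
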