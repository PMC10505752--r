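test_that("spec validation rejects impossible fraction combinations", {
  expect_error(SyntheticImageSpec(levelFractions = c(0.5, 0.3, 0.2, 0.1, 0)),
               "exceed 1")
  expect_error(SyntheticImageSpec(levelFractions = rep(0.1, 5),
                                  artifactFraction = 0.6), "exceed 1")
  expect_error(SyntheticImageSpec(levelFractions = c(-0.1, 0, 0, 0, 0.2)),
               "non-negative")
  expect_error(SyntheticImageSpec(pixelSizeUm = 0), "positive")
})

test_that("an all-negative spec yields a pure background image", {
  out <- generateIHCImage(SyntheticImageSpec(
    40, 40, levelFractions = c(0, 0, 0, 0, 0), artifactFraction = 0,
    seed = 11))
  expect_true(all(intensityValues(out$intensity) >= 176))
  expect_identical(unname(out$groundTruth$totalPositiveArea), 0)
  expect_false(any(out$artifactMask))
})

test_that("ground truth records exact per-level pixel counts by construction", {
  out <- generateIHCImage(SyntheticImageSpec(
    100, 100, pixelSizeUm = 1, levelFractions = c(0, 0, 0, 0, 0.5),
    seed = 5))
  expect_equal(unname(out$groundTruth$levelAreas[["4"]]), 5000)
  # brute-force band membership oracle on the emitted pixels
  v <- intensityValues(out$intensity)
  expect_equal(sum(v <= 70), 5000)
})

test_that("noiseless per-band pixel counts equal ground truth exactly", {
  for (seed in c(1, 7, 42)) {
    out <- generateIHCImage(SyntheticImageSpec(
      80, 60, levelFractions = c(0.1, 0.1, 0.1, 0.1, 0.1),
      noiseSd = 0, seed = seed))
    v <- intensityValues(out$intensity)
    th <- LevelThresholds()
    counts <- vapply(0:4, function(l) {
      band <- v >= th@lower[[as.character(l)]] &
        v <= th@upper[[as.character(l)]] & !out$artifactMask
      sum(band)
    }, numeric(1))
    expect_identical(counts, unname(out$groundTruth$levelPixels))
  }
})

test_that("generation is deterministic for a fixed seed and caller RNG is restored", {
  spec <- SyntheticImageSpec(64, 64, levelFractions = rep(0.1, 5),
                             artifactFraction = 0.1, noiseSd = 3, seed = 99)
  set.seed(123); before <- .Random.seed
  a <- generateIHCImage(spec)
  expect_identical(before, .Random.seed)
  b <- generateIHCImage(spec)
  expect_identical(intensityValues(a$intensity), intensityValues(b$intensity))
  expect_identical(a$rgb, b$rgb)
  expect_identical(a$artifactMask, b$artifactMask)
})

test_that("artifact pixels are reserved-colored and counted in ground truth", {
  out <- generateIHCImage(SyntheticImageSpec(
    50, 50, levelFractions = rep(0.1, 5), artifactFraction = 0.2, seed = 2))
  expect_equal(sum(out$artifactMask), 0.2 * 2500)
  expect_equal(unname(out$groundTruth$artifactArea), 500)
  col <- artifactColor()
  for (c_ in 1:3)
    expect_true(all(out$rgb[, , c_][out$artifactMask] == col[c_]))
})
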