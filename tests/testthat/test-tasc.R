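test_that("tnRatio is the tumor area over the mean control area", {
  expect_equal(tnRatio(1000, c(50, 150)), 10)
  expect_equal(tnRatio(0, c(50, 150)), 0)
  expect_equal(tnRatio(2370, c(100, 100, 37)), 30)
  expect_error(tnRatio(100, c(0, 0)), "zero")
  expect_error(tnRatio(100, numeric(0)), "nonempty")
})

test_that("compartment-wise control averaging is available as an option", {
  ctrl <- data.frame(compartment = c("muscle", "muscle", "dermis"),
                     area = c(10, 30, 80))
  expect_equal(tnRatio(500, ctrl, compartmentMeans = TRUE), 500 / 50)
  expect_equal(tnRatio(500, ctrl$area), 500 / 40)
})

test_that("criteria II and III apply the group-majority decision", {
  expect_equal(criterionII(30, 53), 4L)
  expect_equal(criterionII(5, 16), 0L)
  expect_equal(criterionII(0, 1), 0L)
  expect_equal(criterionIII(11, 22), 3L)   # exactly half still counts
  expect_equal(criterionIII(20, 44), 0L)
  expect_equal(criterionIII(1, 1), 3L)
  expect_error(criterionII(1, 0), "at least 1")
  expect_error(criterionIII(5, 3), "between 0 and")
})

test_that("strict >50% majority mode flips the half-exactly case", {
  expect_equal(criterionIII(11, 22, majorityMode = "gt50"), 0L)
  expect_equal(criterionIII(12, 22, majorityMode = "gt50"), 3L)
  expect_equal(criterionII(8, 16, majorityMode = "gt50"), 0L)
})

test_that("criterion IV bins the rounded integer percentage", {
  expect_equal(criterionIV(92), 6L)
  expect_equal(criterionIV(85), 5L)
  expect_equal(criterionIV(62), 3L)
  expect_equal(criterionIV(49), 0L)
  expect_equal(criterionIV(5), 0L)
  expect_equal(criterionIV(89.5), 6L)   # half-up rounding
  expect_equal(criterionIV(69.4), 3L)
  expect_error(criterionIV(101), "\\[0, 100\\]")
})

test_that("tascScore assembles fixed and evidence-driven criteria", {
  ups <- tascScore(10, 9, 7, 10, 9, group = "UPS")
  expect_equal(tascTotal(ups), 22L)
  expect_equal(unname(tascCriteria(ups)),
               c(5L, 4L, 3L, 6L, 2L, 1L, 1L))
  nos <- tascScore(16, 5, 5, 14, 10, group = "STS NOS")
  expect_equal(tascTotal(nos), 12L)
  # all-zero evidence floors at the fixed criteria
  expect_equal(tascTotal(tascScore(10, 0, 0, 10, 0)), 9L)
})

test_that("the total is bounded in [9, 22] and monotone in the counts", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(1:60, 1); ne <- sample(1:n, 1)
    k2 <- sample(0:n, 1); k3 <- sample(0:ne, 1); k4 <- sample(0:n, 1)
    tot <- tascTotal(tascScore(n, k2, k3, ne, k4))
    expect_gte(tot, 9L); expect_lte(tot, 22L)
    if (k2 < n) expect_gte(tascTotal(tascScore(n, k2 + 1, k3, ne, k4)), tot)
    if (k3 < ne) expect_gte(tascTotal(tascScore(n, k2, k3 + 1, ne, k4)), tot)
    if (k4 < n) expect_gte(tascTotal(tascScore(n, k2, k3, ne, k4 + 1)), tot)
  }
})

test_that("the bundled criterion inputs reproduce the reference report", {
  rep <- tascReport(stsCriterionInputs())
  expect_equal(rep$tasc_total, c(21, 19, 22, 18, 22, 18, 21, 12, 14, 22))
  expect_equal(rep$II, c(4, 4, 4, 4, 4, 4, 4, 0, 0, 4))
  expect_equal(rep$III, c(3, 0, 3, 0, 3, 0, 3, 0, 0, 3))
  expect_equal(rep$IV, c(5, 6, 6, 5, 6, 5, 5, 3, 5, 6))
})

test_that("criterion inputs aggregate correctly from a cohort table", {
  cohort <- data.frame(
    species = "canine", entity = "PWT",
    percent_positive_cells = c(80, 55, 30, 9, 12),
    intensity_grade = c(3, 2, 2, 3, 1),
    tn_ratio = c(20, 5, NA, 15, 11))
  ci <- criterionInputsFromCohort(cohort)
  expect_equal(ci$n_tumors, 5)
  expect_equal(ci$n_diffuse_positive, 2)     # 80 and 55
  expect_equal(ci$n_tn_evaluable, 4)
  expect_equal(ci$n_tn_gt10, 3)
  expect_equal(ci$n_overexpressing, 3)       # 80, 55, 30: >=10% at grade >= 2
  strict <- criterionInputsFromCohort(
    data.frame(species = "s", entity = "e",
               percent_positive_cells = 10, intensity_grade = 2,
               tn_ratio = NA), overexpressionMode = "gt10")
  expect_equal(strict$n_overexpressing, 0)
})
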