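test_that("percentage bins match the published score boundaries", {
  expect_equal(percentageScore(c(0.5, 10, 50, 51)), c(1L, 2L, 3L, 4L))
  expect_equal(percentageScore(0), 1L)
  expect_equal(percentageScore(1), 2L)
  expect_equal(percentageScore(10.5), 3L)  # gap between the printed bins
  expect_equal(percentageScore(100), 4L)
  expect_error(percentageScore(101), "\\[0, 100\\]")
  expect_error(percentageScore(-1), "\\[0, 100\\]")
})

test_that("the final grade is the product, binned into the four categories", {
  expect_equal(finalGrade(4, 3)$final_grade, 12L)
  expect_equal(finalGrade(4, 3)$category, "high")
  expect_equal(finalGrade(3, 2)$final_grade, 6L)
  expect_equal(finalGrade(3, 2)$category, "intermediate")
  expect_equal(finalGrade(2, 0)$final_grade, 0L)
  expect_equal(finalGrade(2, 0)$category, "no_expression")
  expect_error(finalGrade(5, 1), "1-4")
  expect_error(finalGrade(2, 4), "0-3")
})

test_that("grade set closure: only {0,1,2,3,4,6,8,9,12} are reachable", {
  grid <- expand.grid(p = 1:4, i = 0:3)
  fg <- finalGrade(grid$p, grid$i)
  expect_setequal(unique(fg$final_grade), c(0, 1, 2, 3, 4, 6, 8, 9, 12))
  expect_false(any(fg$final_grade %in% c(5, 7, 10, 11)))
  expect_equal(max(fg$final_grade), 12)
  # every grade maps to exactly one category, none to NA
  expect_false(anyNA(fg$category))
  expect_true(all(c("no_expression", "low", "intermediate", "high")
                  %in% fg$category))
})

test_that("category is monotone in both component scores", {
  lvl <- c(no_expression = 0, low = 1, intermediate = 2, high = 3)
  rank_ <- function(p, i) lvl[[finalGrade(p, i)$category]]
  for (p in 1:4) for (i in 0:3) {
    if (p < 4) expect_gte(rank_(p + 1, i), rank_(p, i))
    if (i < 3) expect_gte(rank_(p, i + 1), rank_(p, i))
  }
})

test_that("the hotspot rule selects the strong-signal region past one-third", {
  homogeneous <- data.frame(area_fraction = 1, percent_positive = 35,
                            intensity_grade = 2)
  res <- hotspotAssessment(homogeneous)
  expect_false(res$hotspot)
  expect_equal(res$percent_positive, 35)
  expect_equal(res$intensity_grade, 2)

  hot <- data.frame(area_fraction = c(0.4, 0.6),
                    percent_positive = c(80, 20),
                    intensity_grade = c(3, 1))
  res <- hotspotAssessment(hot)
  expect_true(res$hotspot)
  expect_equal(res$intensity_grade, 3)
  expect_equal(res$percent_positive, 80)

  mild <- data.frame(area_fraction = c(0.2, 0.8),
                     percent_positive = c(80, 20),
                     intensity_grade = c(3, 1))
  res <- hotspotAssessment(mild)
  expect_false(res$hotspot)
  expect_equal(res$intensity_grade, 1)
  expect_equal(res$percent_positive, 0.2 * 80 + 0.8 * 20)

  expect_error(hotspotAssessment(data.frame()), "degenerate")
})

test_that("scoreCohort appends consistent scoring columns", {
  tab <- scoreCohort(generateCohortTable(defaultCohortSpec()[1:2, ],
                                         seed = 5))
  expect_true(all(c("percentage_score", "intensity_score", "final_grade",
                    "category") %in% names(tab)))
  expect_identical(tab$final_grade,
                   tab$percentage_score * tab$intensity_score)
  expect_identical(tab$intensity_score, as.integer(tab$intensity_grade))
})
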