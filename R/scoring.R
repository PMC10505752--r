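#' Percentage score for FAP-positive tumor cells
#'
#' Bins the visually estimated percentage of positive tumor cells into the
#' four-point score: 1+ for under 1% of cells, 2+ for 1% to 10%, 3+ for
#' over 10% up to 50%, and 4+ for over 50%. Continuous inputs strictly
#' between 10 and 11 fall in the 3+ bin (the printed bins jump from "10%"
#' to "11%"; half-open binning keeps the mapping total).
#'
#' @param percentPositive numeric vector in [0, 100]
#' @return integer vector of scores 1-4.
#' @export
#' @examples
#' percentageScore(c(0.5, 10, 50, 51))  # 1 2 3 4
percentageScore <- function(percentPositive) {
  stopIfNot(all(is.finite(percentPositive)) &&
              all(percentPositive >= 0 & percentPositive <= 100),
            "percentPositive must lie in [0, 100]")
  ifelse(percentPositive < 1, 1L,
         ifelse(percentPositive <= 10, 2L,
                ifelse(percentPositive <= 50, 3L, 4L)))
}

#' Expression categories of the final grade of positivity
#'
#' @return named character vector mapping each attainable grade to its
#'   category: 0 is no expression, 1-3 low, 4-6 intermediate, 8-12 high.
#' @export
gradeCategories <- function() {
  g <- c(0, 1, 2, 3, 4, 6, 8, 9, 12)
  structure(ifelse(g == 0, "no_expression",
                   ifelse(g <= 3, "low",
                          ifelse(g <= 6, "intermediate", "high"))),
            names = as.character(g))
}

#' Final grade of positivity from the two component scores
#'
#' The semiquantitative expression score: the percentage score (1-4) is
#' multiplied by the labeling-intensity score (0 none, 1 weak, 2
#' intermediate, 3 strong), and the product is binned into no expression
#' (0), low (1-3), intermediate (4-6), or high (8-12) expression. Grades
#' 5, 7, 10, and 11 are unreachable as products of the score ranges.
#'
#' @param percentageScore integer vector in 1-4
#' @param intensityScore integer vector in 0-3
#' @return data.frame with columns percentage_score, intensity_score,
#'   final_grade, category.
#' @export
#' @examples
#' finalGrade(4, 3)   # grade 12, high
#' finalGrade(3, 2)   # grade 6, intermediate
finalGrade <- function(percentageScore, intensityScore) {
  stopIfNot(all(percentageScore %in% 1:4),
            "percentageScore must be an integer in 1-4")
  stopIfNot(all(intensityScore %in% 0:3),
            "intensityScore must be an integer in 0-3")
  g <- as.integer(percentageScore) * as.integer(intensityScore)
  data.frame(percentage_score = as.integer(percentageScore),
             intensity_score = as.integer(intensityScore),
             final_grade = g,
             category = unname(gradeCategories()[as.character(g)]),
             stringsAsFactors = FALSE)
}

#' Apply the inhomogeneity (hotspot) rule to regional assessments
#'
#' For tumors with inhomogeneous staining: regional summaries (area
#' fraction, percent positive cells, intensity grade) are reduced to one
#' assessment. The area-majority intensity grade is found; if the fraction
#' of tumor area at grades above it exceeds one-third, the assessment is
#' taken from the strong-signal regions (the highest-grade regions
#' present), otherwise from the whole tumor (area-weighted percent
#' positive, area-majority grade).
#'
#' @param regions data.frame with columns area_fraction, percent_positive,
#'   intensity_grade; area fractions must sum to 1
#' @return list with percent_positive, intensity_grade, and hotspot
#'   (logical: whether the strong-signal region was used).
#' @export
#' @examples
#' # 40% of the tumor at grade 3 drives scoring from the hotspot
#' hotspotAssessment(data.frame(area_fraction = c(0.4, 0.6),
#'                              percent_positive = c(80, 20),
#'                              intensity_grade = c(3, 1)))
hotspotAssessment <- function(regions) {
  stopIfNot(is.data.frame(regions) && nrow(regions) >= 1L,
            "degenerate ROI: no tumor regions to assess")
  stopIfNot(all(c("area_fraction", "percent_positive", "intensity_grade")
                %in% names(regions)),
            "regions needs area_fraction, percent_positive, intensity_grade")
  stopIfNot(abs(sum(regions$area_fraction) - 1) < 1e-6,
            "area fractions must sum to 1")
  byGrade <- tapply(regions$area_fraction, regions$intensity_grade, sum)
  majority <- as.integer(names(byGrade)[which.max(byGrade)])
  fracAbove <- sum(regions$area_fraction[regions$intensity_grade > majority])
  if (fracAbove > 1/3) {
    hi <- max(regions$intensity_grade)
    sel <- regions[regions$intensity_grade == hi, , drop = FALSE]
    w <- sel$area_fraction / sum(sel$area_fraction)
    list(percent_positive = sum(w * sel$percent_positive),
         intensity_grade = hi, hotspot = TRUE)
  } else {
    w <- regions$area_fraction
    list(percent_positive = sum(w * regions$percent_positive),
         intensity_grade = majority, hotspot = FALSE)
  }
}

#' Score a cohort table
#'
#' Appends percentage_score, intensity_score, final_grade, and category
#' columns to a per-tumor cohort table carrying percent_positive_cells and
#' intensity_grade columns.
#'
#' @param cohort data.frame with percent_positive_cells and intensity_grade
#' @return the cohort with four scoring columns appended.
#' @export
#' @examples
#' scoreCohort(generateCohortTable(seed = 1))[1:3, ]
scoreCohort <- function(cohort) {
  stopIfNot(all(c("percent_positive_cells", "intensity_grade")
                %in% names(cohort)),
            "cohort needs percent_positive_cells and intensity_grade columns")
  ps <- percentageScore(cohort$percent_positive_cells)
  fg <- finalGrade(ps, cohort$intensity_grade)
  cohort$percentage_score <- fg$percentage_score
  cohort$intensity_score <- fg$intensity_score
  cohort$final_grade <- fg$final_grade
  cohort$category <- fg$category
  cohort
}
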