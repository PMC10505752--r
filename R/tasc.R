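#' Tumor-to-normal ratio for one tumor
#'
#' Divides a tumor's normalized FAP-positive area by the mean normalized
#' FAP-positive area of non-neoplastic tissue (peritumoral and
#' healthy-control compartments) of the matching group. The default pools
#' all control measurements flat; \code{compartmentMeans = TRUE} first
#' averages within each compartment, then across compartments.
#'
#' @param tumorArea normalized positive area of the tumor (um^2 / 2.37 mm^2)
#' @param controlAreas numeric vector of normalized positive control areas,
#'   or with \code{compartmentMeans = TRUE} a data.frame with columns
#'   compartment and area
#' @param compartmentMeans logical, see above
#' @return positive real; 0 when the tumor area is 0.
#' @export
#' @examples
#' tnRatio(1000, c(50, 150))          # 10
#' tnRatio(2370, c(100, 100, 37))     # 30
tnRatio <- function(tumorArea, controlAreas, compartmentMeans = FALSE) {
  stopIfNot(length(tumorArea) == 1L && tumorArea >= 0,
            "tumorArea must be a single non-negative number")
  if (isTRUE(compartmentMeans)) {
    stopIfNot(is.data.frame(controlAreas) &&
                all(c("compartment", "area") %in% names(controlAreas)),
              "compartmentMeans needs a data.frame with compartment and area")
    ctrl <- tapply(controlAreas$area, controlAreas$compartment, mean)
  } else {
    ctrl <- as.numeric(controlAreas)
  }
  stopIfNot(length(ctrl) >= 1L && all(ctrl >= 0),
            "controlAreas must be nonempty and non-negative")
  m <- mean(ctrl)
  if (m <= 0)
    stop("undefined T/N ratio: mean control area is zero", call. = FALSE)
  tumorArea / m
}

majorityMet <- function(k, n, mode = c("gte50", "gt50")) {
  mode <- match.arg(mode)
  stopIfNot(length(n) == 1L && n >= 1L, "denominator must be at least 1")
  stopIfNot(k >= 0 && k <= n, "count must lie between 0 and its denominator")
  f <- k / n
  if (mode == "gte50") f >= 0.5 else f > 0.5
}

#' TASC criterion II: diffuse overexpression through tumor tissue
#'
#' Scores 4 when at least half of the tumors (default majority mode
#' \code{"gte50"}) show FAP staining in at least 50\% of tumor cells,
#' else 0.
#'
#' @param nDiffusePositive number of tumors with >= 50\% positive cells
#' @param nTumors cohort size
#' @param majorityMode "gte50" (default) or strict "gt50"
#' @return integer, 0 or 4.
#' @export
#' @examples
#' criterionII(30, 53)  # 4
#' criterionII(5, 16)   # 0
criterionII <- function(nDiffusePositive, nTumors, majorityMode = "gte50") {
  if (majorityMet(nDiffusePositive, nTumors, majorityMode)) 4L else 0L
}

#' TASC criterion III: tumor-to-normal ratio
#'
#' Scores 3 when the group's ratio is judged above 10, i.e. when at least
#' half (default majority mode) of the evaluable tumors have an individual
#' T/N ratio over 10; else 0.
#'
#' @param nTnGt10 number of evaluable tumors with T/N > 10
#' @param nTnEvaluable number of tumors with an evaluable ratio
#' @param majorityMode "gte50" (default) or strict "gt50"
#' @return integer, 0 or 3.
#' @export
#' @examples
#' criterionIII(11, 22)  # 3 at exactly half
#' criterionIII(20, 44)  # 0
criterionIII <- function(nTnGt10, nTnEvaluable, majorityMode = "gte50") {
  if (majorityMet(nTnGt10, nTnEvaluable, majorityMode)) 3L else 0L
}

#' TASC criterion IV: prevalence of overexpression
#'
#' Bins the integer percentage of patients whose tumors overexpress the
#' target: >= 90\% scores 6, 70-89\% scores 5, 50-69\% scores 3, and below
#' 50\% (including below 10\%) scores 0.
#'
#' @param percentOverexpressing percentage in [0, 100]; non-integer input
#'   is rounded half-up before binning
#' @return integer, 0, 3, 5, or 6.
#' @export
#' @examples
#' criterionIV(92)  # 6
#' criterionIV(85)  # 5
#' criterionIV(62)  # 3
criterionIV <- function(percentOverexpressing) {
  stopIfNot(length(percentOverexpressing) == 1L &&
              is.finite(percentOverexpressing) &&
              percentOverexpressing >= 0 && percentOverexpressing <= 100,
            "percentOverexpressing must lie in [0, 100]")
  p <- roundHalfUp(percentOverexpressing)
  if (p >= 90) 6L else if (p >= 70) 5L else if (p >= 50) 3L else 0L
}

#' Fixed FAP criterion scores
#'
#' Literature-based constants of the rubric for FAP: criterion I
#' (extracellular, cell-surface-bound localization) 5, V (prior in vivo
#' imaging success) 2, VI (enzymatic activity) 1, VII (target-mediated
#' internalization) 1.
#'
#' @return named integer vector.
#' @export
fixedFapCriteria <- function() c(I = 5L, V = 2L, VI = 1L, VII = 1L)

#' Total TASC score for one tumor group
#'
#' Combines the fixed FAP criteria with the evidence-driven criteria II-IV.
#' Criterion IV uses \code{percentOverexpressing} when supplied, otherwise
#' the half-up-rounded percentage \code{100 * nOverexpressing /
#' nTumors}.
#'
#' @param nTumors cohort size
#' @param nDiffusePositive tumors with >= 50\% FAP-positive cells
#' @param nTnGt10 evaluable tumors with T/N ratio > 10
#' @param nTnEvaluable tumors evaluable for the T/N ratio
#' @param nOverexpressing tumors judged FAP-overexpressing (>= 10\% of cells
#'   with intermediate-to-strong staining)
#' @param percentOverexpressing optional explicit percentage for criterion
#'   IV, overriding the count-derived one
#' @param majorityMode "gte50" (default) or "gt50" for criteria II and III
#' @param group label carried into the result
#' @return A \linkS4class{TascResult}.
#' @export
#' @examples
#' tascScore(10, 9, 7, 10, 9, group = "UPS")         # total 22
#' tascScore(16, 5, 5, 14, 10, group = "STS NOS")    # total 12
tascScore <- function(nTumors, nDiffusePositive, nTnGt10, nTnEvaluable,
                      nOverexpressing = NULL, percentOverexpressing = NULL,
                      majorityMode = "gte50", group = "group") {
  stopIfNot(!is.null(nOverexpressing) || !is.null(percentOverexpressing),
            "supply nOverexpressing or percentOverexpressing")
  if (is.null(percentOverexpressing)) {
    stopIfNot(nOverexpressing >= 0 && nOverexpressing <= nTumors,
              "nOverexpressing must lie between 0 and nTumors")
    percentOverexpressing <- 100 * nOverexpressing / nTumors
  }
  fx <- fixedFapCriteria()
  cr <- c(I = fx[["I"]],
          II = criterionII(nDiffusePositive, nTumors, majorityMode),
          III = criterionIII(nTnGt10, nTnEvaluable, majorityMode),
          IV = criterionIV(percentOverexpressing),
          V = fx[["V"]], VI = fx[["VI"]], VII = fx[["VII"]])
  new("TascResult", criteria = cr, total = sum(cr), group = group)
}

#' TASC report for a table of per-group criterion inputs
#'
#' Applies \code{\link{tascScore}} to every row of a criterion-inputs table
#' (such as the bundled \code{\link{stsCriterionInputs}}) and returns a
#' report with per-criterion scores and totals.
#'
#' @param inputs data.frame with columns group, n_tumors,
#'   n_diffuse_positive, n_tn_gt10, n_tn_evaluable, n_overexpressing, and
#'   optionally percent_overexpressing (NA falls back to the counts)
#' @param majorityMode "gte50" (default) or "gt50"
#' @return data.frame with one row per group: criterion scores I-VII and
#'   tasc_total.
#' @export
#' @examples
#' tascReport(stsCriterionInputs())
tascReport <- function(inputs, majorityMode = "gte50") {
  need <- c("group", "n_tumors", "n_diffuse_positive", "n_tn_gt10",
            "n_tn_evaluable", "n_overexpressing")
  stopIfNot(all(need %in% names(inputs)),
            paste("inputs must carry columns:", paste(need, collapse = ", ")))
  rows <- lapply(seq_len(nrow(inputs)), function(i) {
    r <- inputs[i, ]
    pct <- if ("percent_overexpressing" %in% names(inputs) &&
               !is.na(r$percent_overexpressing))
      r$percent_overexpressing else NULL
    res <- tascScore(r$n_tumors, r$n_diffuse_positive, r$n_tn_gt10,
                     r$n_tn_evaluable, r$n_overexpressing,
                     percentOverexpressing = pct,
                     majorityMode = majorityMode, group = r$group)
    cr <- tascCriteria(res)
    data.frame(group = r$group, I = cr[["I"]], II = cr[["II"]],
               III = cr[["III"]], IV = cr[["IV"]], V = cr[["V"]],
               VI = cr[["VI"]], VII = cr[["VII"]],
               tasc_total = tascTotal(res), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bundled criterion inputs for the cross-species STS cohorts
#'
#' Per-group evidence counts for TASC criteria II-IV in the human, canine,
#' and feline soft tissue sarcoma cohorts the package ships as its worked
#' example: cohort sizes, tumors with diffuse (>= 50\% of cells) FAP
#' positivity, evaluable tumors with T/N ratio over 10, and
#' FAP-overexpressing tumors with the reported integer percentage (for the
#' MPNST group the reported percentage, which criterion IV follows, differs
#' from its count).
#'
#' @return data.frame of criterion inputs, one row per species/entity group.
#' @export
#' @examples
#' stsCriterionInputs()
stsCriterionInputs <- function() {
  path <- system.file("extdata", "sts_fap_criterion_inputs.csv",
                      package = "ihcTASC", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Derive criterion inputs from a scored per-tumor cohort table
#'
#' Aggregates a per-tumor table into the evidence counts the TASC rubric
#' consumes, per entity and per species: diffuse positivity is >= 50\%
#' positive cells; a tumor overexpresses when at least 10\% of its cells
#' show intermediate-to-strong (grade >= 2) staining (switchable to a
#' strict > 10\% reading); T/N evaluability is an NA-aware count.
#'
#' @param cohort data.frame with species, entity, percent_positive_cells,
#'   intensity_grade, tn_ratio columns
#' @param overexpressionMode ">= 10\%" (\code{"gte10"}, default) or strict
#'   \code{"gt10"}
#' @return data.frame of criterion inputs (entity rows, then one pooled row
#'   per species with more than one entity).
#' @export
#' @examples
#' criterionInputsFromCohort(generateCohortTable(seed = 1))
criterionInputsFromCohort <- function(cohort,
                                      overexpressionMode = c("gte10", "gt10")) {
  overexpressionMode <- match.arg(overexpressionMode)
  need <- c("species", "entity", "percent_positive_cells", "intensity_grade",
            "tn_ratio")
  stopIfNot(all(need %in% names(cohort)),
            paste("cohort must carry columns:", paste(need, collapse = ", ")))
  over <- if (overexpressionMode == "gte10")
    cohort$percent_positive_cells >= 10 else cohort$percent_positive_cells > 10
  over <- over & cohort$intensity_grade >= 2
  agg <- function(df, label) {
    data.frame(group = label, n_tumors = nrow(df),
               n_diffuse_positive = sum(df$percent_positive_cells >= 50),
               n_tn_gt10 = sum(df$tn_ratio > 10, na.rm = TRUE),
               n_tn_evaluable = sum(!is.na(df$tn_ratio)),
               n_overexpressing = sum(df$over),
               percent_overexpressing = NA_real_, stringsAsFactors = FALSE)
  }
  cohort$over <- over
  out <- list()
  for (sp in unique(cohort$species)) {
    sub <- cohort[cohort$species == sp, ]
    ents <- unique(sub$entity)
    for (e in ents)
      out[[length(out) + 1L]] <- agg(sub[sub$entity == e, ],
                                     paste(sp, e))
    if (length(ents) > 1L)
      out[[length(out) + 1L]] <- agg(sub, paste(sp, "total"))
  }
  do.call(rbind, out)
}
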