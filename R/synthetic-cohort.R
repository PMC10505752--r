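#' Default per-entity cohort specification
#'
#' One row per tumor entity with the study conditions the generator
#' emulates: cohort size, tumor-grade distribution, mean and SD of the
#' visually estimated percent of FAP-positive tumor cells, the distribution
#' over intensity grades 0-3, and the fraction of tumors whose
#' tumor-to-normal ratio exceeds 10 (with the fraction of tumors evaluable
#' for it, i.e. having peritumoral tissue).
#'
#' Percent-positive means and SDs are available per species, so each entity
#' inherits its species values. The DFSP cohort is not graded under the
#' human three-tier scheme and is assigned grade 3 like the other human
#' entities here.
#'
#' @return data.frame, one row per entity.
#' @export
#' @examples
#' defaultCohortSpec()[, c("species", "entity", "n")]
defaultCohortSpec <- function() {
  df <- rbind(
    data.frame(species = "canine", entity = "PWT",     n = 30L,
               grade1 = 21/30, grade2 = 8/30, grade3 = 1/30,
               pctMean = 51.1, pctSd = 36.2,
               tnGt10Frac = 12/23, tnEvalFrac = 23/30),
    data.frame(species = "canine", entity = "STS NOS", n = 16L,
               grade1 = 8/16, grade2 = 7/16, grade3 = 1/16,
               pctMean = 51.1, pctSd = 36.2,
               tnGt10Frac = 5/14, tnEvalFrac = 14/16),
    data.frame(species = "canine", entity = "cFS",     n = 7L,
               grade1 = 4/7, grade2 = 2/7, grade3 = 1/7,
               pctMean = 51.1, pctSd = 36.2,
               tnGt10Frac = 3/7, tnEvalFrac = 1),
    data.frame(species = "feline", entity = "fFS",     n = 24L,
               grade1 = 5/24, grade2 = 17/24, grade3 = 2/24,
               pctMean = 56.6, pctSd = 21.3,
               tnGt10Frac = 11/22, tnEvalFrac = 22/24),
    data.frame(species = "human",  entity = "MPNST",   n = 10L,
               grade1 = 0, grade2 = 2/10, grade3 = 7/10 + 1/10,
               pctMean = 61.1, pctSd = 41.7,
               tnGt10Frac = 3/9, tnEvalFrac = 9/10),
    data.frame(species = "human",  entity = "UPS",     n = 10L,
               grade1 = 0, grade2 = 0, grade3 = 1,
               pctMean = 61.1, pctSd = 41.7,
               tnGt10Frac = 7/10, tnEvalFrac = 1),
    data.frame(species = "human",  entity = "DFSP",    n = 9L,
               grade1 = 0, grade2 = 0, grade3 = 1,
               pctMean = 61.1, pctSd = 41.7,
               tnGt10Frac = 3/7, tnEvalFrac = 7/9),
    data.frame(species = "human",  entity = "MFS",     n = 10L,
               grade1 = 0, grade2 = 0, grade3 = 1,
               pctMean = 61.1, pctSd = 41.7,
               tnGt10Frac = 5/8, tnEvalFrac = 8/10))
  # intensity-grade mix: weak/intermediate/strong shares chosen so roughly
  # two-thirds of tumors reach an intermediate-to-high expression score
  df$int0 <- 0.10; df$int1 <- 0.25; df$int2 <- 0.35; df$int3 <- 0.30
  df
}

#' Generate a synthetic per-tumor cohort table
#'
#' Draws one row per tumor from the per-entity specification: tumor grade
#' from the grade distribution, percent of FAP-positive tumor cells from a
#' normal distribution clipped to [0, 100], an intensity grade from the
#' grade-0-3 distribution, and a tumor-to-normal ratio from a lognormal
#' whose exceedance probability P(T/N > 10) equals the specified fraction
#' (sdlog fixed at 1). Tumors without peritumoral tissue get an NA ratio.
#'
#' The normalized FAP-positive tumor area is generated as a monotone
#' function of percent positivity and intensity grade with lognormal
#' scatter, emulating the strong observed coupling between the visual
#' expression score and the measured stained area.
#'
#' @param spec data.frame as returned by \code{\link{defaultCohortSpec}}
#'   (a subset of rows is fine)
#' @param seed integer RNG seed
#' @return data.frame with columns sample_id, species, entity, grade,
#'   percent_positive_cells, intensity_grade, tn_ratio,
#'   positive_area_norm (um^2 per 2.37 mm^2).
#' @export
#' @examples
#' head(generateCohortTable(defaultCohortSpec(), seed = 1))
generateCohortTable <- function(spec = defaultCohortSpec(), seed = 1L) {
  stopIfNot(is.data.frame(spec) && nrow(spec) >= 1L,
            "spec must be a data.frame with at least one entity row")
  stopIfNot(all(spec$n >= 1L), "every entity must have n >= 1")
  gp <- as.matrix(spec[, c("grade1", "grade2", "grade3")])
  stopIfNot(all(abs(rowSums(gp) - 1) < 1e-9),
            "grade proportions must sum to 1")
  stopIfNot(all(spec$pctMean >= 0 & spec$pctMean <= 100),
            "percent-positive means must lie in [0, 100]")
  withSeed(seed, {
    rows <- lapply(seq_len(nrow(spec)), function(i) {
      r <- spec[i, ]
      n <- r$n
      grade <- sample.int(3L, n, replace = TRUE,
                          prob = c(r$grade1, r$grade2, r$grade3))
      pct <- pmin(pmax(rnorm(n, r$pctMean, r$pctSd), 0), 100)
      ig <- sample(0:3, n, replace = TRUE,
                   prob = c(r$int0, r$int1, r$int2, r$int3))
      sdlog <- 1
      mu <- log(10) + sdlog * qnorm(r$tnGt10Frac)
      tn <- rlnorm(n, meanlog = mu, sdlog = sdlog)
      evaluable <- runif(n) < r$tnEvalFrac
      tn[!evaluable] <- NA_real_
      # stained area rises with both percent positivity and intensity
      area <- hpfArea() * (pct / 100) * (0.25 + 0.18 * ig) *
        rlnorm(n, 0, 0.25)
      data.frame(sample_id = sprintf("%s_%s_%02d", r$species,
                                     gsub("\\s+", "", r$entity), seq_len(n)),
                 species = r$species, entity = r$entity, grade = grade,
                 percent_positive_cells = pct, intensity_grade = ig,
                 tn_ratio = tn, positive_area_norm = area,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
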