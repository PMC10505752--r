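#' Simulate a study bundle: images, masks, ground truth, cohort table
#'
#' Writes a seeded synthetic fixture bundle to \code{outDir}: one RGB PNG
#' plus label-mask PNG per (sample, compartment) pair, a ground-truth CSV
#' with the exact per-level areas of every image, a per-tumor cohort CSV
#' from \code{\link{generateCohortTable}}, and a manifest with checksums.
#' Tumor compartments are simulated with high positive-area fractions,
#' peritumoral and healthy-control compartments with low ones, so the
#' tumor-versus-normal contrast downstream stages measure is real.
#'
#' @param outDir writable output directory (created if missing)
#' @param config pipeline configuration list; see
#'   \code{\link{defaultPipelineConfig}}
#' @param seed integer master seed; every random draw derives from it
#' @param cohortSpec per-entity spec for the cohort table
#' @return invisibly, a list with the ground-truth and cohort data.frames.
#' @export
simulateStudy <- function(outDir, config = defaultPipelineConfig(),
                          seed = 1L, cohortSpec = defaultCohortSpec()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$simulate
  codes <- config$compartment_codes
  ctrlComps <- c("peritumoral_epidermis_dermis", "control_epidermis_dermis",
                 "peritumoral_muscle")
  cohort <- generateCohortTable(cohortSpec, seed = seed)
  gtRows <- list()
  withSeed(seed + 1L, {
    for (sp in unique(cohortSpec$species)) {
      samples <- c(sprintf("%s_tumor_%02d", sp,
                           seq_len(sim$n_tumors_per_species)),
                   sprintf("%s_control_%02d", sp,
                           seq_len(sim$n_controls_per_species)))
      for (s in samples) {
        isTumor <- grepl("_tumor_", s)
        comp <- if (isTumor) "tumor" else sample(ctrlComps, 1L)
        lf <- if (isTumor)
          c(0.25, runif(1, 0.05, 0.15), runif(1, 0.05, 0.15),
            runif(1, 0.05, 0.15), runif(1, 0.1, 0.2))
        else c(0.6, runif(1, 0, 0.05), runif(1, 0, 0.03),
               runif(1, 0, 0.01), runif(1, 0, 0.01))
        spec <- SyntheticImageSpec(
          widthPx = sim$width_px, heightPx = sim$height_px,
          pixelSizeUm = config$pixel_size_um, levelFractions = lf,
          artifactFraction = sim$artifact_fraction, noiseSd = sim$noise_sd,
          seed = sample.int(.Machine$integer.max, 1L))
        out <- generateIHCImage(spec)
        writeRGB(out$rgb, file.path(outDir, paste0(s, "_image.png")))
        labels <- matrix(0L, sim$height_px, sim$width_px)
        labels[roiMask(out$roi)] <- codes[[comp]]
        writeMask(labels, file.path(outDir, paste0(s, "_mask.png")))
        gt <- out$groundTruth
        gtRows[[length(gtRows) + 1L]] <- data.frame(
          sample_id = s, species = sp, compartment = comp,
          area_level0_um2 = gt$levelAreas[["0"]],
          area_level1_um2 = gt$levelAreas[["1"]],
          area_level2_um2 = gt$levelAreas[["2"]],
          area_level3_um2 = gt$levelAreas[["3"]],
          area_level4_um2 = gt$levelAreas[["4"]],
          artifact_area_um2 = gt$artifactArea,
          total_positive_area_um2 = gt$totalPositiveArea,
          roi_area_um2 = gt$roiArea, stringsAsFactors = FALSE)
      }
    }
  })
  groundTruth <- do.call(rbind, gtRows)
  utils::write.csv(groundTruth, file.path(outDir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort, file.path(outDir, "cohort.csv"),
                   row.names = FALSE)
  writeManifest(outDir, seed, config, "simulate")
  invisible(list(groundTruth = groundTruth, cohort = cohort))
}

#' Quantify every image of a study bundle
#'
#' Reads each \code{*_image.png} with its \code{*_mask.png}, detects and
#' excludes artifacts, derives the DAB intensity image by stain unmixing,
#' measures every compartment present in the mask, and writes one CSV row
#' per (sample, compartment). Samples with a missing mask or an unreadable
#' image are skipped with a logged error; the run continues and the
#' failures are reported in the returned summary and the manifest.
#'
#' @param inDir directory produced by \code{\link{simulateStudy}} (or laid
#'   out the same way)
#' @param outDir output directory for quant.csv (default \code{inDir})
#' @param config pipeline configuration list
#' @return invisibly, a list with the quant data.frame and a character
#'   vector of per-sample failures.
#' @export
quantifyStudy <- function(inDir, outDir = inDir,
                          config = defaultPipelineConfig()) {
  images <- list.files(inDir, pattern = "_image\\.png$", full.names = TRUE)
  stopIfNot(length(images) >= 1L,
            sprintf("no inputs: no *_image.png files in %s", inDir))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  th <- configThresholds(config)
  codes <- config$compartment_codes
  failures <- character()
  rows <- list()
  for (imgPath in images) {
    s <- sub("_image\\.png$", "", basename(imgPath))
    maskPath <- file.path(inDir, paste0(s, "_mask.png"))
    if (!file.exists(maskPath)) {
      failures <- c(failures, sprintf("%s: missing mask", s))
      next
    }
    res <- tryCatch({
      rgb <- readRGB(imgPath)
      labels <- readMask(maskPath)
      art <- detectArtifacts(rgb,
                             whiteThreshold = config$artifact$white_threshold,
                             blackThreshold = config$artifact$black_threshold,
                             colorTol = config$artifact$color_tol)
      img <- computeIntensityImage(rgb, stainVectors = rbind(
        hematoxylin = unlist(config$stain_vectors$hematoxylin),
        dab = unlist(config$stain_vectors$dab)),
        pixelSize = config$pixel_size_um)
      present <- setdiff(unique(as.vector(labels)), 0L)
      lapply(present, function(code) {
        comp <- names(codes)[vapply(codes, identical, logical(1),
                                    as.integer(code))]
        roi <- RegionOfInterest(labels == code, compartment = comp,
                                sampleId = s)
        as.data.frame(measureROI(img, roi, th, artifactMask = art,
                                 miPixels = config$mi_pixels))
      })
    }, error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", s, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows <- c(rows, res)
  }
  stopIfNot(length(rows) >= 1L, "no inputs could be quantified")
  quant <- do.call(rbind, rows)
  utils::write.csv(quant, file.path(outDir, "quant.csv"), row.names = FALSE)
  if (length(failures))
    message("quantifyStudy: ", length(failures), " sample(s) skipped:\n  ",
            paste(failures, collapse = "\n  "))
  invisible(list(quant = quant, failures = failures))
}

#' Per-sample tumor-to-normal ratios from a quantification table
#'
#' For every tumor row, divides its normalized positive area by the mean
#' normalized positive area of all peritumoral and control compartment
#' rows of the same species (flat pooling by default; compartment-wise
#' means first when \code{compartmentMeans = TRUE}).
#'
#' @param quant data.frame as written by \code{\link{quantifyStudy}}
#' @param compartmentMeans see \code{\link{tnRatio}}
#' @return data.frame with sample_id, species, tn_ratio.
#' @export
tnRatiosFromQuant <- function(quant, compartmentMeans = FALSE) {
  isTumor <- quant$compartment == "tumor"
  isCtrl <- grepl("^(peritumoral|control)_", quant$compartment)
  # species may be absent from mask-derived rows; recover it from sample ids
  if (!("species" %in% names(quant)) || anyNA(quant$species))
    quant$species <- sub("_.*$", "", quant$sample_id)
  out <- lapply(unique(quant$species[isTumor]), function(sp) {
    ctrl <- quant[isCtrl & quant$species == sp, ]
    stopIfNot(nrow(ctrl) >= 1L,
              sprintf("no control measurements for species '%s'", sp))
    tum <- quant[isTumor & quant$species == sp, ]
    ratios <- vapply(tum$norm_total_positive, function(a) {
      if (compartmentMeans)
        tnRatio(a, data.frame(compartment = ctrl$compartment,
                              area = ctrl$norm_total_positive),
                compartmentMeans = TRUE)
      else tnRatio(a, ctrl$norm_total_positive)
    }, numeric(1))
    data.frame(sample_id = tum$sample_id, species = sp, tn_ratio = ratios,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Score a study: expression scores and TASC report
#'
#' Reads a per-tumor cohort CSV, appends the semiquantitative expression
#' scores, aggregates criterion inputs per entity and species, and writes
#' the TASC report. When a criterion-inputs CSV is supplied instead of a
#' cohort, the report is computed directly from it.
#'
#' @param cohortCsv path to a cohort CSV (or NULL when
#'   \code{criterionInputsCsv} is given)
#' @param outDir output directory
#' @param config pipeline configuration list
#' @param criterionInputsCsv optional per-group criterion-inputs CSV with
#'   the columns of \code{\link{stsCriterionInputs}}
#' @return invisibly, a list with the scored cohort (or NULL) and the TASC
#'   report data.frame.
#' @export
scoreStudy <- function(cohortCsv = NULL, outDir = ".",
                       config = defaultPipelineConfig(),
                       criterionInputsCsv = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  scored <- NULL
  if (!is.null(criterionInputsCsv)) {
    inputs <- utils::read.csv(criterionInputsCsv, stringsAsFactors = FALSE)
  } else {
    stopIfNot(!is.null(cohortCsv) && file.exists(cohortCsv),
              "cohort CSV not found")
    cohort <- utils::read.csv(cohortCsv, stringsAsFactors = FALSE)
    if (nrow(cohort) == 0L) {
      warning("empty cohort: writing empty report")
      empty <- data.frame()
      utils::write.csv(empty, file.path(outDir, "tasc_report.csv"),
                       row.names = FALSE)
      return(invisible(list(scored = empty, tasc = empty)))
    }
    scored <- scoreCohort(cohort)
    utils::write.csv(scored, file.path(outDir, "expression_scores.csv"),
                     row.names = FALSE)
    inputs <- criterionInputsFromCohort(
      scored, overexpressionMode = config$overexpression_mode)
  }
  tasc <- tascReport(inputs, majorityMode = config$majority_mode)
  utils::write.csv(tasc, file.path(outDir, "tasc_report.csv"),
                   row.names = FALSE)
  lines <- c("TASC target-suitability report",
             sprintf("  majority rule: %s; overexpression rule: %s",
                     config$majority_mode, config$overexpression_mode),
             sprintf("  %-16s II=%d III=%d IV=%d  total %2d / 22",
                     tasc$group, tasc$II, tasc$III, tasc$IV,
                     tasc$tasc_total))
  writeLines(lines, file.path(outDir, "tasc_summary.txt"))
  invisible(list(scored = scored, tasc = tasc))
}

#' Statistical report on pipeline outputs
#'
#' Mirrors the study's reporting stage on the pipeline's own CSVs:
#' Kruskal-Wallis with Dunn post-hoc on normalized positive areas and mean
#' intensities across tissue classes (tumor vs peritumoral vs control),
#' Spearman correlation of stained area with the final grade of positivity,
#' and a chi-squared test of expression category against species. Writes a
#' tidy CSV of test results and a Markdown summary.
#'
#' @param quantCsv path to quant.csv from \code{\link{quantifyStudy}}
#' @param scoresCsv optional expression_scores.csv from
#'   \code{\link{scoreStudy}}
#' @param outDir output directory
#' @return invisibly, the results data.frame.
#' @export
statsReport <- function(quantCsv, scoresCsv = NULL, outDir = ".") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  quant <- utils::read.csv(quantCsv, stringsAsFactors = FALSE)
  cls <- ifelse(quant$compartment == "tumor", "tumor",
                ifelse(grepl("^peritumoral_", quant$compartment),
                       "peritumoral",
                       ifelse(grepl("^control_", quant$compartment),
                              "control", "inflammation")))
  rows <- list()
  addRow <- function(comparison, test, statistic, p)
    rows[[length(rows) + 1L]] <<- data.frame(
      comparison = comparison, test = test, statistic = statistic,
      p_value = p, stringsAsFactors = FALSE)
  if (length(unique(cls)) >= 2L) {
    a <- compareGroups(quant$norm_total_positive, cls)
    addRow("normalized positive area by tissue class", a@test,
           a@statistic, a@pValue)
    m <- compareGroups(quant$mean_intensity, cls)
    addRow("mean intensity by tissue class", m@test, m@statistic, m@pValue)
  }
  md <- c("# Statistical report", "",
          sprintf("Inputs: %d measured regions (%s).", nrow(quant),
                  paste(sort(unique(cls)), collapse = ", ")))
  if (!is.null(scoresCsv) && file.exists(scoresCsv)) {
    sc <- utils::read.csv(scoresCsv, stringsAsFactors = FALSE)
    if (all(c("positive_area_norm", "final_grade") %in% names(sc))) {
      ct <- correlate(sc$positive_area_norm, sc$final_grade)
      addRow("stained area vs final grade of positivity",
             "Spearman", ct$rho, ct$p_value)
      md <- c(md, "", sprintf(
        "Spearman rho (stained area vs final grade): %.3f (p = %.3g).",
        ct$rho, ct$p_value))
    }
    if (all(c("category", "species") %in% names(sc)) &&
        length(unique(sc$species)) >= 2L) {
      tab <- table(sc$species, sc$category)
      tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
      if (nrow(tab) >= 2L && ncol(tab) >= 2L) {
        x <- categoricalTest(tab)
        addRow("expression category by species", x@test, x@statistic,
               x@pValue)
      }
    }
  }
  results <- do.call(rbind, rows)
  utils::write.csv(results, file.path(outDir, "stats_report.csv"),
                   row.names = FALSE)
  md <- c(md, "", "| comparison | test | statistic | p |",
          "|---|---|---|---|",
          sprintf("| %s | %s | %.4g | %.4g |", results$comparison,
                  results$test, results$statistic, results$p_value))
  writeLines(md, file.path(outDir, "stats_report.md"))
  invisible(results)
}

#' Run the full pipeline: simulate, quantify, score, report
#'
#' @param outDir output directory for all stages
#' @param seed integer master seed
#' @param config pipeline configuration list
#' @return invisibly, a list with the per-stage outputs.
#' @export
#' @examples
#' \donttest{
#' out <- runPipeline(file.path(tempdir(), "ihc-run"), seed = 1)
#' out$score$tasc
#' }
runPipeline <- function(outDir, seed = 1L,
                        config = defaultPipelineConfig()) {
  sim <- simulateStudy(outDir, config, seed)
  quant <- quantifyStudy(outDir, outDir, config)
  tn <- tnRatiosFromQuant(quant$quant)
  utils::write.csv(tn, file.path(outDir, "tn_ratios.csv"), row.names = FALSE)
  score <- scoreStudy(file.path(outDir, "cohort.csv"), outDir, config)
  stats <- statsReport(file.path(outDir, "quant.csv"),
                       file.path(outDir, "expression_scores.csv"), outDir)
  invisible(list(simulate = sim, quant = quant, tn = tn, score = score,
                 stats = stats))
}
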