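#' @rdname IntensityImage-class
#' @param object,x an object
#' @export
setGeneric("intensityValues", function(object) standardGeneric("intensityValues"))

#' @rdname IntensityImage-class
#' @export
setMethod("intensityValues", "IntensityImage", function(object) object@values)

#' @rdname IntensityImage-class
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname IntensityImage-class
#' @export
setMethod("pixelSize", "IntensityImage", function(object) object@pixelSize)

#' @rdname RegionOfInterest-class
#' @param object an object
#' @export
setGeneric("roiMask", function(object) standardGeneric("roiMask"))

#' @rdname RegionOfInterest-class
#' @export
setMethod("roiMask", "RegionOfInterest", function(object) object@mask)

#' @rdname RegionOfInterest-class
#' @export
setGeneric("compartment", function(object) standardGeneric("compartment"))

#' @rdname RegionOfInterest-class
#' @export
setMethod("compartment", "RegionOfInterest", function(object) object@compartment)

#' @rdname QuantResult-class
#' @param object an object
#' @export
setGeneric("levelAreas", function(object) standardGeneric("levelAreas"))

#' @rdname QuantResult-class
#' @export
setMethod("levelAreas", "QuantResult", function(object) object@levelAreas)

#' @rdname QuantResult-class
#' @export
setGeneric("normalizedAreas", function(object) standardGeneric("normalizedAreas"))

#' @rdname QuantResult-class
#' @export
setMethod("normalizedAreas", "QuantResult", function(object) object@normalizedAreas)

#' @rdname QuantResult-class
#' @export
setGeneric("meanIntensity", function(object) standardGeneric("meanIntensity"))

#' @rdname QuantResult-class
#' @export
setMethod("meanIntensity", "QuantResult", function(object) object@meanIntensity)

#' @rdname QuantResult-class
#' @export
setGeneric("artifactArea", function(object) standardGeneric("artifactArea"))

#' @rdname QuantResult-class
#' @export
setMethod("artifactArea", "QuantResult", function(object) object@artifactArea)

#' @rdname QuantResult-class
#' @export
setGeneric("roiArea", function(object) standardGeneric("roiArea"))

#' @rdname QuantResult-class
#' @export
setMethod("roiArea", "QuantResult", function(object) object@roiArea)

#' @rdname QuantResult-class
#' @export
setGeneric("totalPositiveArea", function(object) standardGeneric("totalPositiveArea"))

#' @rdname QuantResult-class
#' @export
setMethod("totalPositiveArea", "QuantResult", function(object) object@totalPositiveArea)

#' @rdname TascResult-class
#' @param object an object
#' @export
setGeneric("tascCriteria", function(object) standardGeneric("tascCriteria"))

#' @rdname TascResult-class
#' @export
setMethod("tascCriteria", "TascResult", function(object) object@criteria)

#' @rdname TascResult-class
#' @export
setGeneric("tascTotal", function(object) standardGeneric("tascTotal"))

#' @rdname TascResult-class
#' @export
setMethod("tascTotal", "TascResult", function(object) object@total)

#' Coerce a QuantResult to a one-row data.frame
#'
#' @param x a \linkS4class{QuantResult}
#' @param row.names,optional,... ignored, present for generic compatibility
#' @return data.frame with one row per region: metadata, per-level and
#'   normalized areas, artifact area, and mean intensity.
#' @export
as.data.frame.QuantResult <- function(x, row.names = NULL, optional = FALSE, ...) {
  la <- x@levelAreas; na <- x@normalizedAreas
  data.frame(sample_id = x@sampleId, compartment = x@compartment,
             species = x@species, entity = x@entity,
             roi_area_um2 = x@roiArea, artifact_area_um2 = x@artifactArea,
             area_level0_um2 = la[["0"]], area_level1_um2 = la[["1"]],
             area_level2_um2 = la[["2"]], area_level3_um2 = la[["3"]],
             area_level4_um2 = la[["4"]],
             total_positive_area_um2 = x@totalPositiveArea,
             norm_level1 = na[["1"]], norm_level2 = na[["2"]],
             norm_level3 = na[["3"]], norm_level4 = na[["4"]],
             norm_total_positive = na[["total"]],
             mean_intensity = x@meanIntensity,
             stringsAsFactors = FALSE)
}

setMethod("show", "IntensityImage", function(object) {
  d <- dim(object@values)
  cat(sprintf("IntensityImage: %d x %d px, %.3g um/px, values %d-%d\n",
              d[1], d[2], object@pixelSize,
              min(object@values), max(object@values)))
})

setMethod("show", "RegionOfInterest", function(object) {
  cat(sprintf("RegionOfInterest '%s' (%s): %d px in mask\n",
              object@sampleId, object@compartment, sum(object@mask)))
})

setMethod("show", "LevelThresholds", function(object) {
  cat("LevelThresholds (pixel-value bands, lower value = stronger DAB):\n")
  lab <- c("background", "weak", "intermediate", "strong", "very strong")
  for (i in seq_len(5L))
    cat(sprintf("  level %d (%s): [%d, %d]\n", i - 1L, lab[i],
                object@lower[i], object@upper[i]))
})

setMethod("show", "QuantResult", function(object) {
  cat(sprintf("QuantResult '%s' (%s)\n", object@sampleId, object@compartment))
  cat(sprintf("  ROI %.0f um2, artifact %.0f um2, positive %.0f um2 (%.1f%%)\n",
              object@roiArea, object@artifactArea, object@totalPositiveArea,
              100 * object@totalPositiveArea /
                max(object@roiArea - object@artifactArea, .Machine$double.eps)))
  cat(sprintf("  normalized positive %.0f um2 / 2.37 mm2, MI %.1f\n",
              object@normalizedAreas[["total"]], object@meanIntensity))
})

setMethod("show", "TascResult", function(object) {
  cat(sprintf("TascResult [%s]: ", object@group))
  cat(paste(names(object@criteria), object@criteria, sep = "=",
            collapse = " "))
  cat(sprintf("  total = %d / 22\n", object@total))
})

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%d groups)\n", object@test,
              object@statistic, object@pValue, length(object@groups)))
  if (nrow(object@pairwise))
    cat(sprintf("  %d pairwise comparisons (adjusted)\n",
                nrow(object@pairwise)))
})
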