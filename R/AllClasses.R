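#' @import methods
NULL

#' Tissue compartment vocabulary
#'
#' The fixed set of tissue compartments a region of interest may be tagged
#' with: the tumor itself, the three peritumoral tissue types sampled around
#' it, the matching healthy-control tissue types, and inflamed tissue.
#'
#' @return Character vector of valid compartment labels.
#' @export
#' @examples
#' compartmentLevels()
compartmentLevels <- function() {
  c("tumor",
    "peritumoral_epidermis_dermis", "peritumoral_adipose", "peritumoral_muscle",
    "control_epidermis_dermis", "control_adipose", "control_muscle",
    "inflammation")
}

#' IntensityImage: per-pixel DAB staining intensity
#'
#' A single-channel image of integer pixel values in [0, 255] where lower
#' values represent stronger brown (DAB) staining, together with the physical
#' pixel size. This is the working representation all level classification
#' and area measurement operates on.
#'
#' @slot values integer matrix, pixel values in [0, 255]
#' @slot pixelSize positive numeric, micrometers per pixel edge
#'
#' @export
setClass("IntensityImage",
  representation(values = "matrix", pixelSize = "numeric"))

setValidity("IntensityImage", function(object) {
  v <- object@values
  if (length(v) == 0L) return("image must contain at least one pixel")
  if (anyNA(v)) return("pixel values must not be NA")
  if (min(v) < 0 || max(v) > 255) return("pixel values must lie in [0, 255]")
  if (any(v != round(v))) return("pixel values must be integers")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a single positive number")
  TRUE
})

#' Construct an IntensityImage
#'
#' @param values numeric or integer matrix of pixel values in [0, 255]
#' @param pixelSize micrometers per pixel edge (default 1)
#' @return An \linkS4class{IntensityImage}.
#' @export
#' @examples
#' img <- IntensityImage(matrix(200L, 10, 10), pixelSize = 0.5)
#' dim(intensityValues(img))
IntensityImage <- function(values, pixelSize = 1) {
  storage.mode(values) <- "integer"
  new("IntensityImage", values = values, pixelSize = as.numeric(pixelSize))
}

#' RegionOfInterest: labeled pixel mask for one tissue compartment
#'
#' A boolean mask congruent with its image, tagged with the tissue
#' compartment it delineates and sample metadata.
#'
#' @slot mask logical matrix; TRUE marks pixels inside the region
#' @slot compartment one of \code{compartmentLevels()}
#' @slot sampleId character sample identifier
#' @slot species character, e.g. "human", "canine", "feline"
#' @slot entity character tumor entity label (may be NA for controls)
#'
#' @export
setClass("RegionOfInterest",
  representation(mask = "matrix", compartment = "character",
                 sampleId = "character", species = "character",
                 entity = "character"))

setValidity("RegionOfInterest", function(object) {
  if (!is.logical(object@mask)) return("mask must be a logical matrix")
  if (!any(object@mask)) return("mask must contain at least one TRUE pixel")
  if (!(object@compartment %in% compartmentLevels()))
    return(sprintf("unknown compartment '%s'", object@compartment))
  TRUE
})

#' Construct a RegionOfInterest
#'
#' @param mask logical matrix (TRUE = inside region)
#' @param compartment tissue compartment, one of \code{compartmentLevels()}
#' @param sampleId,species,entity sample metadata strings
#' @return A \linkS4class{RegionOfInterest}.
#' @export
RegionOfInterest <- function(mask, compartment = "tumor", sampleId = "sample",
                             species = NA_character_, entity = NA_character_) {
  new("RegionOfInterest", mask = mask, compartment = compartment,
      sampleId = sampleId, species = species, entity = entity)
}

#' LevelThresholds: pixel-value bands for the five staining levels
#'
#' Closed integer intervals assigning every pixel value in [0, 255] to
#' exactly one staining level: level 0 is background (FAP-negative), levels
#' 1-4 are weak, intermediate, strong, and very strong immunoreactivity.
#' Lower pixel values mean stronger brown staining, so lower bands carry
#' higher levels.
#'
#' @slot lower integer vector of lower bounds, named "0".."4"
#' @slot upper integer vector of upper bounds, named "0".."4"
#'
#' @export
setClass("LevelThresholds",
  representation(lower = "integer", upper = "integer"))

setValidity("LevelThresholds", function(object) {
  lo <- object@lower; hi <- object@upper
  if (length(lo) != 5L || length(hi) != 5L)
    return("exactly five bands (levels 0-4) are required")
  if (!identical(names(lo), as.character(0:4)) ||
      !identical(names(hi), as.character(0:4)))
    return("bands must be named '0'..'4'")
  if (any(lo > hi)) return("each band must satisfy lower <= upper")
  # disjoint and covering [0, 255]
  covered <- rep(FALSE, 256L)
  for (i in seq_len(5L)) {
    idx <- (lo[i]:hi[i]) + 1L
    if (any(covered[idx])) return("bands overlap")
    covered[idx] <- TRUE
  }
  if (!all(covered)) return("bands must cover every value in [0, 255]")
  TRUE
})

#' Construct level thresholds
#'
#' Defaults are the study bands: level 1 (weak) 131-175, level 2
#' (intermediate) 101-130, level 3 (strong) 71-100, level 4 (very strong)
#' 0-70, background 176-255. The value 176 is assigned to background so the
#' bands cover [0, 255] with the printed level-1 upper bound intact.
#'
#' @param level1,level2,level3,level4,background length-2 integer vectors
#'   c(lower, upper)
#' @return A \linkS4class{LevelThresholds}.
#' @export
#' @examples
#' th <- LevelThresholds()
#' classifyLevels(IntensityImage(matrix(c(60L, 150L, 200L), 1)), th)
LevelThresholds <- function(level1 = c(131L, 175L), level2 = c(101L, 130L),
                            level3 = c(71L, 100L), level4 = c(0L, 70L),
                            background = c(176L, 255L)) {
  b <- rbind(background, level1, level2, level3, level4)
  new("LevelThresholds",
      lower = structure(as.integer(b[, 1]), names = as.character(0:4)),
      upper = structure(as.integer(b[, 2]), names = as.character(0:4)))
}

#' QuantResult: per-region quantification of DAB staining
#'
#' Holds the per-level stained areas of one region of interest, the excluded
#' artifact area, the total FAP-positive area (sum of levels 1-4), areas
#' normalized to 10 high-power fields (2.37 mm^2), and the mean staining
#' intensity (MI) over non-artifact pixels.
#'
#' @slot levelAreas numeric length 5, named "0".."4", micrometers^2
#' @slot artifactArea numeric, excluded area in micrometers^2
#' @slot roiArea numeric, full region area in micrometers^2
#' @slot totalPositiveArea numeric, sum of level 1-4 areas
#' @slot normalizedAreas numeric length 6 named "0".."4","total", areas per
#'   2.37 mm^2 of artifact-free tissue
#' @slot meanIntensity numeric in [0, 255]
#' @slot sampleId,compartment,species,entity character metadata
#'
#' @export
setClass("QuantResult",
  representation(levelAreas = "numeric", artifactArea = "numeric",
                 roiArea = "numeric", totalPositiveArea = "numeric",
                 normalizedAreas = "numeric", meanIntensity = "numeric",
                 sampleId = "character", compartment = "character",
                 species = "character", entity = "character"))

setValidity("QuantResult", function(object) {
  if (length(object@levelAreas) != 5L) return("levelAreas must have length 5")
  if (any(object@levelAreas < 0) || object@artifactArea < 0)
    return("areas must be non-negative")
  tol <- 1e-6 * max(1, object@roiArea)
  if (abs(sum(object@levelAreas) + object@artifactArea - object@roiArea) > tol)
    return("level areas plus artifact area must equal the ROI area")
  if (abs(sum(object@levelAreas[as.character(1:4)]) -
          object@totalPositiveArea) > tol)
    return("totalPositiveArea must equal the sum of level 1-4 areas")
  if (!is.na(object@meanIntensity) &&
      (object@meanIntensity < 0 || object@meanIntensity > 255))
    return("meanIntensity must lie in [0, 255] (NA only when no pixel qualifies)")
  TRUE
})

#' TascResult: criterion scores and total of the TASC rubric
#'
#' Seven-criterion target selection criteria score for an imaging target in
#' one tumor group. Criteria I (extracellular localization), V (prior in
#' vivo imaging), VI (enzymatic activity), and VII (internalization) are
#' literature-based constants for FAP; II (diffuse overexpression), III
#' (tumor-to-normal ratio), and IV (prevalence of overexpression) are
#' computed from cohort evidence. Maximum total 22.
#'
#' @slot criteria integer length 7, named "I".."VII"
#' @slot total integer, sum of the criteria
#' @slot group character label (species / entity)
#'
#' @export
setClass("TascResult",
  representation(criteria = "integer", total = "integer", group = "character"))

setValidity("TascResult", function(object) {
  if (length(object@criteria) != 7L) return("seven criteria required")
  if (!identical(names(object@criteria),
                 c("I", "II", "III", "IV", "V", "VI", "VII")))
    return("criteria must be named I..VII")
  if (sum(object@criteria) != object@total)
    return("total must equal the sum of the criterion scores")
  if (object@total > 22L) return("total cannot exceed 22")
  TRUE
})

#' ComparisonResult: outcome of a group comparison or categorical test
#'
#' @slot test character, test name
#' @slot statistic numeric test statistic
#' @slot pValue numeric in [0, 1]
#' @slot pairwise data.frame of pairwise comparisons (possibly empty) with
#'   unadjusted and adjusted p-values
#' @slot groups character vector of group labels
#'
#' @export
setClass("ComparisonResult",
  representation(test = "character", statistic = "numeric",
                 pValue = "numeric", pairwise = "data.frame",
                 groups = "character"))

setValidity("ComparisonResult", function(object) {
  if (is.na(object@pValue) || object@pValue < 0 || object@pValue > 1)
    return("pValue must lie in [0, 1]")
  TRUE
})
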