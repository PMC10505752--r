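#' Classify pixels into the five staining-intensity levels
#'
#' Assigns each pixel the unique level whose closed pixel-value band
#' contains it: with the default bands, values 0-70 are level 4 (very
#' strong), 71-100 level 3 (strong), 101-130 level 2 (intermediate),
#' 131-175 level 1 (weak), and 176-255 level 0 (background, FAP-negative).
#'
#' @param img an \linkS4class{IntensityImage} (or integer matrix)
#' @param thresholds a \linkS4class{LevelThresholds}; validated before use
#' @return integer matrix of levels 0-4, congruent with the image.
#' @export
#' @examples
#' classifyLevels(IntensityImage(matrix(c(70L, 71L, 176L), 1)))
classifyLevels <- function(img, thresholds = LevelThresholds()) {
  validObject(thresholds)
  v <- if (is(img, "IntensityImage")) intensityValues(img) else img
  lut <- integer(256L)
  for (i in seq_len(5L))
    lut[(thresholds@lower[i]:thresholds@upper[i]) + 1L] <- i - 1L
  matrix(lut[as.integer(v) + 1L], nrow = nrow(v))
}

#' Detect artifacts in an RGB image by simple rules
#'
#' Flags pixels to exclude from all area and mean-intensity computations:
#' saturated white (glass, all channels at or above \code{whiteThreshold}),
#' near-black debris (all channels at or below \code{blackThreshold}), and
#' the reserved synthetic artifact color (within \code{colorTol} of pure
#' magenta per channel).
#'
#' @param rgb h x w x 3 array of 8-bit RGB values
#' @param roi optional \linkS4class{RegionOfInterest}; the returned mask is
#'   restricted to the region
#' @param whiteThreshold,blackThreshold channel cutoffs for glass / debris
#' @param colorTol per-channel tolerance around the reserved color
#' @return logical matrix, TRUE where a pixel is an artifact.
#' @export
detectArtifacts <- function(rgb, roi = NULL, whiteThreshold = 250,
                            blackThreshold = 10, colorTol = 5) {
  stopIfNot(is.array(rgb) && length(dim(rgb)) == 3L && dim(rgb)[3] == 3L,
            "artifact detection requires an h x w x 3 RGB array")
  if (max(rgb) <= 1) rgb <- rgb * 255
  r <- rgb[, , 1]; g <- rgb[, , 2]; b <- rgb[, , 3]
  white <- r >= whiteThreshold & g >= whiteThreshold & b >= whiteThreshold
  black <- r <= blackThreshold & g <= blackThreshold & b <= blackThreshold
  col <- artifactColor()
  reserved <- abs(r - col[1]) <= colorTol & abs(g - col[2]) <= colorTol &
    abs(b - col[3]) <= colorTol
  mask <- white | black | reserved
  if (!is.null(roi)) mask <- mask & roiMask(roi)
  mask
}

#' Standardized reporting area: 10 high-power fields
#'
#' One x400 high-power field covers 0.237 mm^2; measured areas are
#' normalized to 10 HPF = 2.37 mm^2 = 2,370,000 um^2 so regions of
#' different sizes are comparable.
#'
#' @return numeric, 2,370,000 (um^2).
#' @export
hpfArea <- function() 2.37e6

#' Quantify DAB staining within one region of interest
#'
#' Measures per-level stained areas (pixel counts times the squared pixel
#' size), excludes artifacts, sums levels 1-4 into the total FAP-positive
#' area, normalizes all areas to 10 high-power fields (2.37 mm^2) of
#' artifact-free tissue, and computes the mean staining intensity (MI).
#'
#' Normalization multiplies each area by
#' \code{hpfArea() / (roiArea - artifactArea)}, i.e. areas are expressed per
#' 2.37 mm^2 of evaluable tissue; the artifact area is subtracted from the
#' denominator so non-tissue does not dilute positivity.
#'
#' @param img an \linkS4class{IntensityImage}
#' @param roi a \linkS4class{RegionOfInterest} congruent with the image
#' @param thresholds a \linkS4class{LevelThresholds}
#' @param artifactMask optional logical matrix of pixels to exclude
#' @param miPixels "all" (default) computes MI over all non-artifact region
#'   pixels; "positive" restricts it to level 1-4 pixels
#' @return A \linkS4class{QuantResult}.
#' @export
#' @examples
#' img <- IntensityImage(matrix(200L, 50, 50))
#' roi <- RegionOfInterest(matrix(TRUE, 50, 50))
#' measureROI(img, roi)
measureROI <- function(img, roi, thresholds = LevelThresholds(),
                       artifactMask = NULL,
                       miPixels = c("all", "positive")) {
  miPixels <- match.arg(miPixels)
  v <- intensityValues(img)
  m <- roiMask(roi)
  stopIfNot(identical(dim(v), dim(m)), "image and ROI mask must be congruent")
  if (is.null(artifactMask)) artifactMask <- matrix(FALSE, nrow(v), ncol(v))
  stopIfNot(identical(dim(v), dim(artifactMask)),
            "artifact mask must be congruent with the image")
  px2 <- pixelSize(img)^2
  inArt <- m & artifactMask
  inTissue <- m & !artifactMask
  if (!any(inTissue))
    stop("degenerate ROI: every pixel is an artifact, MI undefined",
         call. = FALSE)
  lv <- classifyLevels(img, thresholds)
  counts <- vapply(0:4, function(l) sum(lv[inTissue] == l), numeric(1))
  names(counts) <- as.character(0:4)
  levelAreas <- counts * px2
  artArea <- sum(inArt) * px2
  roiA <- sum(m) * px2
  totalPos <- sum(levelAreas[as.character(1:4)])
  normFactor <- hpfArea() / (roiA - artArea)
  normalized <- c(levelAreas, total = totalPos) * normFactor
  names(normalized) <- c(as.character(0:4), "total")
  miPix <- if (miPixels == "all") v[inTissue] else v[inTissue & lv >= 1]
  mi <- if (length(miPix)) mean(miPix) else NA_real_
  new("QuantResult", levelAreas = levelAreas, artifactArea = artArea,
      roiArea = roiA, totalPositiveArea = totalPos,
      normalizedAreas = normalized, meanIntensity = mi,
      sampleId = roi@sampleId, compartment = roi@compartment,
      species = roi@species, entity = roi@entity)
}
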