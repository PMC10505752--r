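#' Specification for a synthetic DAB-stained image
#'
#' Describes an image whose per-level positive-area fractions, artifact
#' fraction, and pixel noise are known exactly, so the quantification stage
#' can be tested against ground truth.
#'
#' @param widthPx,heightPx image dimensions in pixels
#' @param pixelSizeUm micrometers per pixel edge
#' @param levelFractions five non-negative target area fractions for levels
#'   0 (stained-tissue background) through 4; any remaining fraction is
#'   unstained background tissue (also level 0 after classification)
#' @param artifactFraction fraction of pixels rendered as artifacts, in [0, 1)
#' @param noiseSd Gaussian pixel-value noise standard deviation
#' @param seed integer RNG seed; the generator is deterministic given it
#' @return list of class "SyntheticImageSpec".
#' @export
#' @examples
#' spec <- SyntheticImageSpec(100, 100, levelFractions = rep(0.1, 5))
SyntheticImageSpec <- function(widthPx = 128, heightPx = 128,
                               pixelSizeUm = 1,
                               levelFractions = c(0.3, 0.1, 0.1, 0.1, 0.1),
                               artifactFraction = 0, noiseSd = 0,
                               seed = 1L) {
  lf <- as.numeric(levelFractions)
  stopIfNot(length(lf) == 5L && all(lf >= 0),
            "levelFractions must be five non-negative reals")
  stopIfNot(artifactFraction >= 0 && artifactFraction < 1,
            "artifactFraction must lie in [0, 1)")
  stopIfNot(sum(lf) + artifactFraction <= 1 + 1e-12,
            "levelFractions plus artifactFraction must not exceed 1")
  stopIfNot(pixelSizeUm > 0, "pixelSizeUm must be positive")
  stopIfNot(noiseSd >= 0, "noiseSd must be non-negative")
  structure(list(widthPx = as.integer(widthPx),
                 heightPx = as.integer(heightPx),
                 pixelSizeUm = pixelSizeUm, levelFractions = lf,
                 artifactFraction = artifactFraction, noiseSd = noiseSd,
                 seed = as.integer(seed)),
            class = "SyntheticImageSpec")
}

# representative pixel value at the center of each level band; far enough
# from every band edge that noiseSd = 5 essentially never crosses a
# positive/background boundary
levelCenters <- function(thresholds = LevelThresholds()) {
  ctr <- floor((thresholds@lower + thresholds@upper) / 2)
  ctr[["0"]] <- 215L   # stained-tissue background kept below saturated white
  ctr
}

#' Generate a synthetic DAB-stained IHC image with known ground truth
#'
#' Pixels are assigned to the five intensity levels (and to artifacts) in
#' exact counts derived from the spec fractions, placed at the center pixel
#' value of each level band, optionally perturbed by Gaussian noise
#' (rounded, clipped to [0, 255]). The image is returned both as the
#' intensity channel (consumed directly via the pass-through mode of
#' \code{\link{computeIntensityImage}}) and as an RGB brightfield rendering
#' via \code{\link{renderDAB}}, with artifacts in the reserved color.
#'
#' @param spec a \code{\link{SyntheticImageSpec}}
#' @param thresholds level bands to target; default study bands
#' @return list with elements \code{intensity} (\linkS4class{IntensityImage}),
#'   \code{rgb} (h x w x 3 array), \code{roi} (full-frame tumor
#'   \linkS4class{RegionOfInterest}), \code{artifactMask} (logical matrix),
#'   and \code{groundTruth} (list: per-level pixel counts and areas in um^2,
#'   artifact pixel count and area).
#' @export
#' @examples
#' out <- generateIHCImage(SyntheticImageSpec(64, 64, seed = 7))
#' out$groundTruth$levelAreas
generateIHCImage <- function(spec, thresholds = LevelThresholds()) {
  stopIfNot(inherits(spec, "SyntheticImageSpec"),
            "spec must be a SyntheticImageSpec")
  n <- spec$widthPx * spec$heightPx
  nArt <- round(spec$artifactFraction * n)
  nLev <- round(spec$levelFractions * n)
  # positive levels 1-4 keep their rounded counts; everything left over is
  # level-0 background so counts always sum to n
  over <- sum(nLev[-1]) + nArt - n
  if (over > 0) nLev[-1] <- pmax(nLev[-1] - over, 0)
  nLev[1] <- n - sum(nLev[-1]) - nArt

  withSeed(spec$seed, {
    ord <- sample.int(n)
    centers <- levelCenters(thresholds)
    classes <- rep.int(c(0:4, -1L), times = c(nLev, nArt))
    cls <- integer(n)
    cls[ord] <- classes
    vals <- numeric(n)
    for (l in 0:4) vals[cls == l] <- centers[[as.character(l)]]
    if (spec$noiseSd > 0) {
      tissue <- cls >= 0L
      vals[tissue] <- vals[tissue] + rnorm(sum(tissue), sd = spec$noiseSd)
    }
    vals[cls == -1L] <- 255   # placeholder; artifacts carry the reserved color
    vals <- pmin(pmax(round(vals), 0), 255)
    vmat <- matrix(as.integer(vals), nrow = spec$heightPx)
    amat <- matrix(cls == -1L, nrow = spec$heightPx)

    px2 <- spec$pixelSizeUm^2
    gt <- list(levelPixels = structure(nLev, names = as.character(0:4)),
               levelAreas = structure(nLev * px2, names = as.character(0:4)),
               artifactPixels = nArt, artifactArea = nArt * px2,
               totalPositiveArea = sum(nLev[2:5]) * px2,
               roiArea = n * px2)
    list(intensity = IntensityImage(vmat, pixelSize = spec$pixelSizeUm),
         rgb = renderDAB(vmat, artifactMask = amat),
         roi = RegionOfInterest(matrix(TRUE, spec$heightPx, spec$widthPx),
                                compartment = "tumor"),
         artifactMask = amat,
         groundTruth = gt)
  })
}
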