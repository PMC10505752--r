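#' Standard H-DAB stain vectors
#'
#' Published Ruifrok-Johnston optical-density unit vectors for hematoxylin
#' and DAB, used by the default stain-unmixing intensity method. Rows are
#' stains, columns R, G, B.
#'
#' @return 2 x 3 numeric matrix with rows "hematoxylin", "dab".
#' @export
#' @examples
#' hdabVectors()
hdabVectors <- function() {
  m <- rbind(hematoxylin = c(0.650, 0.704, 0.286),
             dab         = c(0.268, 0.570, 0.776))
  m / sqrt(rowSums(m^2))
}

#' Derive a DAB intensity image from an RGB brightfield image
#'
#' Converts an 8-bit RGB immunohistochemistry image to a single-channel
#' intensity map in [0, 255] where lower values represent stronger brown
#' (DAB) chromogen staining. The default method unmixes the DAB component
#' by standard color deconvolution: per-channel optical density
#' \eqn{OD_c = -log10(I_c / 255)} is projected onto the DAB stain vector to
#' give a DAB density d, which is mapped back to a transmission-scale pixel
#' value \eqn{round(255 * 10^{-d})}. The mapping is strictly decreasing in
#' DAB density, so stronger staining always yields a lower value; a pure
#' white pixel maps to 255.
#'
#' Pass-through mode accepts a single-channel matrix (or an
#' \linkS4class{IntensityImage}) and returns it unchanged; synthetic images
#' generated by \code{\link{generateIHCImage}} carry their intensity channel
#' directly and use this mode.
#'
#' @param image either an h x w x 3 array of 8-bit RGB values (0-255, or
#'   0-1 which is rescaled), or for \code{method = "passthrough"} a numeric
#'   matrix / IntensityImage of values in [0, 255]
#' @param method "deconvolution" (default) or "passthrough"
#' @param stainVectors 2 x 3 stain OD matrix, rows hematoxylin and DAB;
#'   default \code{hdabVectors()}
#' @param pixelSize micrometers per pixel edge attached to the result
#' @return An \linkS4class{IntensityImage}.
#' @export
#' @examples
#' px <- array(255, dim = c(2, 2, 3))        # pure white
#' intensityValues(computeIntensityImage(px))  # all 255
computeIntensityImage <- function(image,
                                  method = c("deconvolution", "passthrough"),
                                  stainVectors = hdabVectors(),
                                  pixelSize = 1) {
  method <- match.arg(method)
  if (is(image, "IntensityImage")) {
    stopIfNot(method == "passthrough",
              "an IntensityImage input requires method = 'passthrough'")
    return(image)
  }
  if (method == "passthrough") {
    stopIfNot(is.matrix(image),
              "pass-through mode expects a single-channel matrix")
    return(IntensityImage(round(image), pixelSize = pixelSize))
  }
  stopIfNot(is.array(image) && length(dim(image)) == 3L && dim(image)[3] == 3L,
            "deconvolution requires an h x w x 3 RGB array")
  if (max(image) <= 1) image <- image * 255
  dab <- stainVectors["dab", ]
  dab <- dab / sqrt(sum(dab^2))
  od <- -log10(pmax(image, 1) / 255)
  d <- od[, , 1, drop = FALSE] * dab[1] + od[, , 2, drop = FALSE] * dab[2] +
    od[, , 3, drop = FALSE] * dab[3]
  v <- matrix(round(255 * 10^(-pmax(d, 0))), nrow = dim(image)[1])
  IntensityImage(pmin(pmax(v, 0), 255), pixelSize = pixelSize)
}

#' Render a DAB intensity map as an RGB brightfield image
#'
#' Inverse of the default unmixing in \code{\link{computeIntensityImage}}:
#' each intensity value v is assigned the DAB optical density
#' \eqn{d = -log10(max(v, 0.5) / 255)} and rendered along the DAB stain
#' vector as \eqn{I_c = round(255 * 10^{-d s_c})}. Pixels flagged in
#' \code{artifactMask} are painted the reserved artifact color (pure
#' magenta), which the brown rendering can never produce.
#'
#' @param values integer matrix of intensity values in [0, 255]
#' @param artifactMask optional logical matrix; TRUE pixels become artifacts
#' @param stainVectors stain OD matrix as in \code{hdabVectors()}
#' @return h x w x 3 array of 8-bit RGB values.
#' @export
renderDAB <- function(values, artifactMask = NULL,
                      stainVectors = hdabVectors()) {
  dab <- stainVectors["dab", ]
  dab <- dab / sqrt(sum(dab^2))
  lut <- vapply(0:255, function(v) {
    d <- -log10(max(v, 0.5) / 255)
    pmin(pmax(round(255 * 10^(-d * dab)), 0), 255)
  }, numeric(3))                       # 3 x 256
  idx <- as.integer(values) + 1L
  out <- array(0, dim = c(dim(values), 3L))
  for (c_ in 1:3) out[, , c_] <- matrix(lut[c_, idx], nrow = nrow(values))
  if (!is.null(artifactMask) && any(artifactMask)) {
    col <- artifactColor()
    for (c_ in 1:3) {
      plane <- out[, , c_]
      plane[artifactMask] <- col[c_]
      out[, , c_] <- plane
    }
  }
  out
}

#' Reserved artifact color
#'
#' Pure magenta; unreachable by the brown DAB rendering, so synthetic
#' artifacts are unambiguous for the rule-based detector.
#'
#' @return integer RGB triple.
#' @export
artifactColor <- function() c(255L, 0L, 255L)
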