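#' Write an RGB image to PNG
#'
#' @param rgb h x w x 3 array of 8-bit values (0-255)
#' @param path output file path
#' @return the path, invisibly.
#' @export
writeRGB <- function(rgb, path) {
  png::writePNG(rgb / 255, target = path)
  invisible(path)
}

#' Read an RGB image from PNG or TIFF
#'
#' @param path image file; .png or .tif/.tiff (TIFF requires the tiff
#'   package)
#' @return h x w x 3 array of 8-bit values in 0-255.
#' @export
readRGB <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    tiff::readTIFF(path)
  } else png::readPNG(path)
  if (length(dim(img)) == 2L)
    stop("expected an RGB image, got a single channel; use readMask()",
         call. = FALSE)
  round(img[, , 1:3, drop = FALSE] * 255)
}

#' Write a label mask as a single-channel PNG
#'
#' Label 0 marks pixels outside any region; positive integer codes mark
#' compartments (the code-to-compartment map travels in the run config).
#'
#' @param labels integer matrix of small non-negative codes
#' @param path output file path
#' @return the path, invisibly.
#' @export
writeMask <- function(labels, path) {
  stopIfNot(max(labels) <= 255, "label codes must fit 8 bits")
  png::writePNG(labels / 255, target = path)
  invisible(path)
}

#' Read a label mask PNG
#'
#' @param path single-channel PNG written by \code{\link{writeMask}}
#' @return integer matrix of label codes.
#' @export
readMask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  round(img * 255)
}

#' Rasterize a polygon region to a logical mask
#'
#' Even-odd rasterization over pixel centers with 0-based vertex
#' coordinates (x right, y down), for regions supplied as polygon JSON
#' rather than label masks.
#'
#' @param xs,ys polygon vertex coordinates in pixel units
#' @param width,height output mask dimensions
#' @return logical matrix (rows = y, columns = x).
#' @export
#' @examples
#' sum(polygonMask(c(0, 10, 10, 0), c(0, 0, 10, 10), 20, 20))
polygonMask <- function(xs, ys, width, height) {
  stopIfNot(length(xs) == length(ys) && length(xs) >= 3L,
            "a polygon needs at least three vertices")
  cx <- rep(seq_len(width) - 0.5, each = height)
  cy <- rep(seq_len(height) - 0.5, times = width)
  n <- length(xs)
  inside <- rep(FALSE, length(cx))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((ys[i] > cy) != (ys[j] > cy)) &
      (cx < (xs[j] - xs[i]) * (cy - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  matrix(inside, nrow = height)
}

#' Default pipeline configuration
#'
#' All tunable settings of the pipeline in one list: level thresholds, the
#' 10-HPF normalization constant, majority and overexpression rule modes,
#' stain vectors, pixel size, artifact detector cutoffs, and the synthetic
#' bundle layout. \code{readPipelineConfig()} loads a YAML file over these
#' defaults.
#'
#' @return named list of settings.
#' @export
defaultPipelineConfig <- function() {
  th <- LevelThresholds()
  list(
    thresholds = list(lower = as.list(th@lower), upper = as.list(th@upper)),
    hpf_area_um2 = hpfArea(),
    majority_mode = "gte50",
    overexpression_mode = "gte10",
    mi_pixels = "all",
    pixel_size_um = 1,
    stain_vectors = list(hematoxylin = as.numeric(hdabVectors()[1, ]),
                         dab = as.numeric(hdabVectors()[2, ])),
    artifact = list(white_threshold = 250, black_threshold = 10,
                    color_tol = 5),
    compartment_codes = as.list(structure(seq_along(compartmentLevels()),
                                          names = compartmentLevels())),
    simulate = list(width_px = 96, height_px = 96, noise_sd = 0,
                    artifact_fraction = 0.05, n_tumors_per_species = 4,
                    n_controls_per_species = 2))
}

#' Read a pipeline configuration YAML over the defaults
#'
#' @param path YAML file; missing keys fall back to
#'   \code{\link{defaultPipelineConfig}}
#' @return named list of settings.
#' @export
readPipelineConfig <- function(path = NULL) {
  cfg <- defaultPipelineConfig()
  if (!is.null(path)) {
    stopIfNot(file.exists(path), sprintf("config file not found: %s", path))
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

configThresholds <- function(cfg) {
  lo <- unlist(cfg$thresholds$lower); hi <- unlist(cfg$thresholds$upper)
  LevelThresholds(level1 = c(lo[["1"]], hi[["1"]]),
                  level2 = c(lo[["2"]], hi[["2"]]),
                  level3 = c(lo[["3"]], hi[["3"]]),
                  level4 = c(lo[["4"]], hi[["4"]]),
                  background = c(lo[["0"]], hi[["0"]]))
}

#' Write a machine-readable run manifest
#'
#' Records the seed, package version, configuration, and MD5 checksums of
#' the stage's output files so a re-run can be verified byte-for-byte.
#'
#' @param dir directory whose files are checksummed
#' @param seed integer seed used by the stage
#' @param config the configuration list in force
#' @param stage stage name
#' @return path of the written manifest.json, invisibly.
#' @export
writeManifest <- function(dir, seed, config, stage) {
  files <- setdiff(list.files(dir, recursive = TRUE), "manifest.json")
  sums <- tools::md5sum(file.path(dir, files))
  manifest <- list(stage = stage, seed = seed,
                   package_version = as.character(
                     utils::packageVersion("ihcTASC")),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      usetz = TRUE),
                   config = config,
                   checksums = as.list(structure(unname(sums),
                                                 names = files)))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
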