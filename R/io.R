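# TIFF and sidecar I/O. Stacks are multi-page 16-bit TIFFs; physical units,
# metadata and the processing log travel in a JSON sidecar next to the
# image (<path>.json). Intensities are quantized to integers only here.

.sidecarPath <- function(path) paste0(path, ".json")

#' Write an SHG stack to a multi-page TIFF
#'
#' Intensities are rounded to integers and stored as 16-bit; voxel sizes,
#' metadata and the processing log go to a JSON sidecar at
#' \code{<path>.json}.
#'
#' @param s an \code{ShgStack}.
#' @param path output TIFF path.
#' @return Invisibly, \code{path}.
#' @export
writeStack <- function(s, path) {
  slices <- lapply(stackSlices(s@intensities),
                   function(m) round(pmin(pmax(m, 0), 65535)) / 65535)
  tiff::writeTIFF(slices, path, bits.per.sample = 16L, compression = "none")
  meta <- list(kind = "ShgStack",
               voxel_um = as.list(s@voxelUm),
               normal_axis = s@normalAxis,
               meta = list(surface = s@meta@surface,
                           distance_from_tip_cm = s@meta@distanceFromTipCm,
                           specimen_id = s@meta@specimenId),
               processing_log = s@processingLog)
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an SHG stack from a multi-page TIFF
#'
#' Values are loaded as stored (clipping is a pipeline stage, never an I/O
#' side effect). Voxel sizes come from the JSON sidecar or the
#' \code{voxelUm} argument; with neither, the function refuses to guess
#' units.
#'
#' @param path TIFF path.
#' @param voxelUm optional explicit voxel sizes (y, x, z) in um.
#' @return An \code{ShgStack}.
#' @export
readStack <- function(path, voxelUm = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- slicesToStack(lapply(pages, function(m) m * 1.0))
  sc <- .sidecarPath(path)
  meta <- sampleMeta(); normalAxis <- "y"; plog <- list()
  if (file.exists(sc)) {
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (is.null(voxelUm) && !is.null(side$voxel_um))
      voxelUm <- unlist(side$voxel_um)
    if (!is.null(side$normal_axis)) normalAxis <- side$normal_axis
    if (!is.null(side$meta))
      meta <- sampleMeta(side$meta$surface, side$meta$distance_from_tip_cm,
                         side$meta$specimen_id)
    if (!is.null(side$processing_log))
      plog <- if (is.data.frame(side$processing_log))
        split(side$processing_log, seq_len(nrow(side$processing_log)))
      else as.list(side$processing_log)
  }
  if (is.null(voxelUm))
    stop("voxel size unknown: no JSON sidecar next to ", path,
         " and no voxelUm given; refusing to assume units")
  shgStack(arr, voxelUm = voxelUm, normalAxis = normalAxis, meta = meta,
           processingLog = plog)
}

#' Write a layer-label mask as a single-page TIFF
#'
#' Labels (0 background, 1 SC, 2 VE, 3 D) stored 8-bit; pixel size and
#' metadata go to a JSON sidecar.
#'
#' @param img a \code{LayerImage}.
#' @param path output TIFF path.
#' @return Invisibly, \code{path}.
#' @export
writeMask <- function(img, path) {
  tiff::writeTIFF(img@labels / 255, path, bits.per.sample = 8L,
                  compression = "none")
  meta <- list(kind = "LayerImage",
               pixel_size_mm = img@pixelSizeMm,
               normal_axis = img@normalAxis,
               meta = list(surface = img@meta@surface,
                           distance_from_tip_cm = img@meta@distanceFromTipCm,
                           specimen_id = img@meta@specimenId))
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a layer-label mask
#'
#' @param path TIFF path.
#' @param pixelSizeMm optional explicit pixel size; otherwise taken from the
#'   sidecar (an error if neither is available). Unknown label values are a
#'   format error.
#' @return A \code{LayerImage}.
#' @export
readMask <- function(path, pixelSizeMm = NULL) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  meta <- sampleMeta(); normalAxis <- "y"
  sc <- .sidecarPath(path)
  if (file.exists(sc)) {
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (is.null(pixelSizeMm) && !is.null(side$pixel_size_mm))
      pixelSizeMm <- side$pixel_size_mm
    if (!is.null(side$normal_axis)) normalAxis <- side$normal_axis
    if (!is.null(side$meta))
      meta <- sampleMeta(side$meta$surface, side$meta$distance_from_tip_cm,
                         side$meta$specimen_id)
  }
  if (is.null(pixelSizeMm))
    stop("pixel size unknown: no JSON sidecar next to ", path,
         " and no pixelSizeMm given")
  layerImage(m, pixelSizeMm, normalAxis = normalAxis, meta = meta)
}

#' Default pipeline configuration
#'
#' Every stage parameter defaults to the standard analysis setting: clip
#' range (0, 4000), blur sigma 0.5 px, rolling-ball radius 40 px, ten
#' intensity ROIs of 200 x 250 um, four orientation ROIs of 600 x 450 um,
#' 150 px boundary margins, +-5 degree angle windows, a 200 x 200 px by
#' 100 um crossing ROI, and the 1.21 / 10.62 um voxel geometry.
#'
#' @return A nested named list.
#' @export
defaultConfig <- function() {
  list(
    seed = 1L,
    voxel_um = list(y = 1.21, x = 1.21, z = 10.62),
    pixel_size_mm = 0.01,
    clip = list(lo = 0, hi = 4000),
    blur_sigma_px = 0.5,
    ball_radius_px = 40,
    intensity = list(n_rois = 10L, size_um = c(200, 250), margin_px = 150L,
                     project = TRUE),
    orientation = list(n_rois = 4L, size_um = c(600, 450), margin_px = 150L,
                       use_rois = TRUE, keep_fraction = 0.06,
                       min_length_um = 20, radius_um = 5,
                       perp_halfwidth_deg = 5, par_halfwidth_deg = 5,
                       bin_width_deg = 5),
    crossings = list(roi_px = c(200L, 200L), depth_um = 100,
                     min_cross_angle_deg = 15, decluster_factor = 2),
    synthesize = list(enabled = TRUE,
                      mask_width_px = 1000L,
                      stack_shape_px = c(1400L, 1100L, 1L),
                      crossing_shape_px = c(280L, 280L, 10L),
                      n_fibers = 87L,
                      n_crossing_fibers = 36L,
                      crossing_fiber_length_um = 150,
                      planted_crossings = 12L,
                      intensity_ratio = 2,
                      intensity_scale = 600,
                      noise_sigma = 30))
}

#' Scaled-down demonstration configuration
#'
#' The same stage defaults as \code{\link{defaultConfig}} but on a coarser,
#' smaller synthetic geometry so the full pipeline runs in seconds: 2.42 um
#' in-plane pixels, 288 px stacks, six 200 x 250 um intensity ROIs with a
#' 20 px margin, and whole-stack orientation analysis.
#'
#' @return A nested named list.
#' @export
demoConfig <- function() {
  cfg <- defaultConfig()
  cfg$voxel_um <- list(y = 2.42, x = 2.42, z = 10.62)
  cfg$intensity$n_rois <- 5L
  cfg$intensity$margin_px <- 20L
  cfg$orientation$use_rois <- FALSE
  cfg$synthesize$stack_shape_px <- c(360L, 360L, 4L)
  cfg$synthesize$crossing_shape_px <- c(200L, 200L, 6L)
  cfg$synthesize$n_fibers <- 48L
  cfg$synthesize$n_crossing_fibers <- 14L
  cfg$synthesize$planted_crossings <- 5L
  cfg$crossings$roi_px <- c(160L, 160L)
  cfg
}

#' Read / write a pipeline configuration
#'
#' YAML round-trips losslessly: serialize, parse, serialize is a fixed
#' point.
#'
#' @param path YAML file path.
#' @return \code{readConfig} returns the configuration list.
#' @export
readConfig <- function(path) yaml::read_yaml(path)

#' @rdname readConfig
#' @param cfg configuration list.
#' @export
writeConfig <- function(cfg, path) {
  writeLines(yaml::as.yaml(cfg), path)
  invisible(path)
}

#' Reference layer-thickness table
#'
#' Mean and sd layer thickness (mm) of stratum corneum, viable epidermis and
#' dermis at eight trunk sites, used as generator defaults for layered
#' phantoms.
#'
#' @return data.frame with surface, distance_cm and per-layer mean/sd
#'   columns.
#' @export
trunkReferenceThickness <- function() {
  data.frame(
    surface = c(rep("dorsal", 5), rep("ventral", 3)),
    distance_cm = c(3, 27, 81, 100, 133, 27, 51, 133),
    SC_mm = c(0.39, 0.17, 0.39, 0.87, 1.8, 0.29, 0.12, 0.34),
    SC_sd_mm = c(0.11, 0.16, 0.27, 0.61, 0.68, 0.22, 0.18, 0.22),
    VE_mm = c(0.05, 0.36, 0.27, 0.58, 0.42, 0.50, 0.32, 0.22),
    VE_sd_mm = c(0.05, 0.21, 0.21, 0.51, 0.36, 0.31, 0.29, 0.22),
    D_mm = c(0.8, 1.5, 6.6, 5.8, 5.4, 2.4, 4.9, 4.2),
    D_sd_mm = c(0.09, 0.27, 0.28, 0.90, 0.64, 0.44, 0.54, 0.23))
}
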