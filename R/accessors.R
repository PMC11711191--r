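#' Stack intensities
#'
#' @param x an \code{ShgStack}.
#' @return The 3D intensity array (y, x, z).
#' @rdname intensities
#' @export
setMethod("intensities", "ShgStack", function(x) x@intensities)

#' Voxel sizes
#'
#' @param x an \code{ShgStack}.
#' @return Named numeric (y, x, z), um per voxel.
#' @rdname voxelUm
#' @export
setMethod("voxelUm", "ShgStack", function(x) x@voxelUm)

#' Layer label matrix
#'
#' @param x a \code{LayerImage}.
#' @return Integer matrix of layer codes.
#' @rdname layerLabels
#' @export
setMethod("layerLabels", "LayerImage", function(x) x@labels)

#' Pixel size
#'
#' @param x a \code{LayerImage} or \code{ThicknessProfile}.
#' @return Pixel size in mm.
#' @rdname pixelSizeMm
#' @export
setMethod("pixelSizeMm", "LayerImage", function(x) x@pixelSizeMm)

#' @rdname pixelSizeMm
#' @export
setMethod("pixelSizeMm", "ThicknessProfile", function(x) x@pixelSizeMm)

#' Fiber polylines
#'
#' @param x a \code{FiberSet}.
#' @return List of n x 3 matrices (y, x, z in um).
#' @rdname fibers
#' @export
setMethod("fibers", "FiberSet", function(x) x@fibers)

#' Per-fiber angles
#'
#' @param x a \code{FiberSet} or \code{PhantomTruth}.
#' @return Numeric angles in [0, 180), degrees from the outward normal.
#' @rdname fiberAngles
#' @export
setMethod("fiberAngles", "FiberSet", function(x) x@angleDeg)

#' @rdname fiberAngles
#' @export
setMethod("fiberAngles", "PhantomTruth", function(x) x@fiberAnglesDeg)

#' Number of fibers
#'
#' @param x a \code{FiberSet} or \code{OrientationSummary}.
#' @return Integer count.
#' @rdname nFibers
#' @export
setMethod("nFibers", "FiberSet", function(x) length(x@fibers))

#' @rdname nFibers
#' @export
setMethod("nFibers", "OrientationSummary", function(x) x@nFibers)

#' Processing log
#'
#' @param x an \code{ShgStack}.
#' @return List of applied operations, in order, with parameters.
#' @rdname processingLog
#' @export
setMethod("processingLog", "ShgStack", function(x) x@processingLog)

#' Sample metadata accessor
#'
#' @param x an object carrying a \code{SampleMeta}.
#' @return The \code{SampleMeta}.
#' @rdname sampleMetadata
#' @export
setMethod("sampleMetadata", "ShgStack", function(x) x@meta)

#' @rdname sampleMetadata
#' @export
setMethod("sampleMetadata", "LayerImage", function(x) x@meta)

#' @rdname sampleMetadata
#' @export
setMethod("sampleMetadata", "ThicknessProfile", function(x) x@meta)

#' @rdname sampleMetadata
#' @export
setMethod("sampleMetadata", "IntensityResult", function(x) x@meta)

setMethod("show", "ShgStack", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("ShgStack: %d x %d x %d voxels (%.3g x %.3g x %.3g um)\n",
              d[1], d[2], d[3], object@voxelUm[1], object@voxelUm[2],
              object@voxelUm[3]))
  cat(sprintf("  %s surface, %.1f cm from tip; %d processing step(s)\n",
              object@meta@surface, object@meta@distanceFromTipCm,
              length(object@processingLog)))
})

setMethod("show", "LayerImage", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LayerImage: %d x %d px at %.4g mm/px (%s, %.1f cm)\n",
              d[1], d[2], object@pixelSizeMm, object@meta@surface,
              object@meta@distanceFromTipCm))
  tab <- table(factor(object@labels, levels = 0:3,
                      labels = c("background", LAYER_NAMES)))
  cat("  pixels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "FiberSet", function(object) {
  n <- length(object@fibers)
  cat(sprintf("FiberSet: %d fiber(s)\n", n))
  if (n) cat(sprintf("  angle range [%.1f, %.1f] deg from outward normal\n",
                     min(object@angleDeg), max(object@angleDeg)))
})

setMethod("show", "OrientationSummary", function(object) {
  if (object@nFibers == 0) {
    cat("OrientationSummary: no fibers\n")
  } else {
    cat(sprintf(
      "OrientationSummary: n=%d, %.1f%% perpendicular, %.1f%% parallel, %s\n",
      object@nFibers, object@pctPerpendicular, object@pctParallel,
      if (isTRUE(object@bimodal)) "bimodal" else "not bimodal"))
  }
})

setMethod("show", "ThicknessProfile", function(object) {
  s <- thicknessSummary(object)
  cat(sprintf("ThicknessProfile over %d strips (%s, %.1f cm):\n",
              length(object@perStripMm$SC), object@meta@surface,
              object@meta@distanceFromTipCm))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s: %.3g +- %.2g mm\n", s$layer[i], s$mean_mm[i],
                s$sd_mm[i]))
})

setMethod("show", "IntensityResult", function(object) {
  cat(sprintf("IntensityResult: %d ROI(s), grand mean %.4g +- %.3g %s\n",
              length(object@perRoiMean), object@grandMean, object@grandSd,
              object@units))
})

setMethod("show", "CrossingResult", function(object) {
  cat(sprintf("CrossingResult: %d crossing(s)", object@crossingCount))
  if (!is.na(object@roiVolumeUm3))
    cat(sprintf(" in %.4g um^3 (density %.3g per um^3)",
                object@roiVolumeUm3, object@densityPerUm3))
  cat("\n")
})

setMethod("show", "StatResult", function(object) {
  cat(sprintf("%s: t = %.3g, p = %.3g (%s); n = %s\n", object@testName,
              object@statistic, object@pValue, object@stars,
              paste(object@nPerGroup, collapse = "/")))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf(
    "PhantomTruth: layers (mm) %s; %d fibers, weights %s; seed %d\n",
    paste(sprintf("%s=%.3g", names(object@layerThicknessMm),
                  object@layerThicknessMm), collapse = " "),
    object@nFibers,
    paste(sprintf("%.2g", object@mixtureWeights), collapse = "/"),
    object@seed))
})
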