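#' @rdname intensities
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname voxelUm
#' @export
setGeneric("voxelUm", function(x) standardGeneric("voxelUm"))

#' @rdname layerLabels
#' @export
setGeneric("layerLabels", function(x) standardGeneric("layerLabels"))

#' @rdname pixelSizeMm
#' @export
setGeneric("pixelSizeMm", function(x) standardGeneric("pixelSizeMm"))

#' @rdname fibers
#' @export
setGeneric("fibers", function(x) standardGeneric("fibers"))

#' @rdname fiberAngles
#' @export
setGeneric("fiberAngles", function(x) standardGeneric("fiberAngles"))

#' @rdname nFibers
#' @export
setGeneric("nFibers", function(x) standardGeneric("nFibers"))

#' @rdname processingLog
#' @export
setGeneric("processingLog", function(x) standardGeneric("processingLog"))

#' @rdname sampleMetadata
#' @export
setGeneric("sampleMetadata", function(x) standardGeneric("sampleMetadata"))

#' @rdname clipRange
#' @export
setGeneric("clipRange", function(x, lo = 0, hi = 4000)
  standardGeneric("clipRange"))

#' @rdname gaussianBlur
#' @export
setGeneric("gaussianBlur", function(x, sigmaPx = 0.5)
  standardGeneric("gaussianBlur"))

#' @rdname rollingBallSubtract
#' @export
setGeneric("rollingBallSubtract", function(x, radiusPx = 40)
  standardGeneric("rollingBallSubtract"))

#' @rdname extractFibers
#' @export
setGeneric("extractFibers", function(x, keepFraction = 0.06,
                                     minLengthUm = 20, radiusUm = 5, ...)
  standardGeneric("extractFibers"))
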