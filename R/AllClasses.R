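#' @import methods
NULL

LAYER_NAMES <- c("SC", "VE", "D")
LAYER_CODES <- c(background = 0L, SC = 1L, VE = 2L, D = 3L)
MIXTURE_NAMES <- c("perpendicular", "parallel", "diffuse")

#' Sample metadata
#'
#' Identifies a tissue site: trunk surface (dorsal or ventral) and distance
#' from the trunk tip in centimetres.
#'
#' @slot surface character, "dorsal" or "ventral".
#' @slot distanceFromTipCm numeric, non-negative distance from the trunk tip.
#' @slot specimenId character identifier.
#' @exportClass SampleMeta
setClass("SampleMeta",
  representation(surface = "character", distanceFromTipCm = "numeric",
                 specimenId = "character"),
  prototype(surface = "dorsal", distanceFromTipCm = 0, specimenId = "phantom"),
  validity = function(object) {
    if (!object@surface %in% c("dorsal", "ventral"))
      return("surface must be 'dorsal' or 'ventral'")
    if (length(object@distanceFromTipCm) != 1 || is.na(object@distanceFromTipCm) ||
        object@distanceFromTipCm < 0)
      return("distanceFromTipCm must be a single non-negative number")
    TRUE
  })

#' Construct sample metadata
#'
#' @param surface "dorsal" or "ventral".
#' @param distanceFromTipCm distance from the trunk tip (cm), >= 0.
#' @param specimenId free-text specimen identifier.
#' @return A \code{SampleMeta} object.
#' @export
sampleMeta <- function(surface = "dorsal", distanceFromTipCm = 0,
                       specimenId = "phantom") {
  new("SampleMeta", surface = surface,
      distanceFromTipCm = as.numeric(distanceFromTipCm),
      specimenId = specimenId)
}

#' Phantom ground truth
#'
#' Generator parameters and emitted ground truth for synthetic phantoms:
#' layered histology masks and fibrous SHG-like stacks. The same object is
#' both the recipe (parameters) and, after generation, the oracle (the exact
#' per-fiber angle list and realized crossing count).
#'
#' @slot layerThicknessMm named numeric (SC, VE, D) mean thickness in mm.
#' @slot boundaryUndulationMm amplitude of the sinusoidal layer-boundary
#'   perturbation (mm).
#' @slot undulationPeriods number of full undulation periods across the
#'   image width (integer-valued so per-column means stay centred).
#' @slot fiberAnglesDeg true in-plane fiber angles in [0, 180), degrees from
#'   the outward normal; filled in by the generator.
#' @slot mixtureWeights named fractions (perpendicular, parallel, diffuse)
#'   summing to 1.
#' @slot nFibers number of fibers to draw.
#' @slot fiberRadiusUm tube radius in um (default 5, i.e. 10 um thick fibers).
#' @slot fiberLengthUm fiber length in um; \code{NA} (default) extends every
#'   fiber across the full field of view.
#' @slot plantedCrossingCount crossings to plant; \code{NA} leaves crossing
#'   geometry unconstrained.
#' @slot intensityScale mean on-fiber intensity (arbitrary units, 12-bit).
#' @slot noiseSigma Gaussian read-noise standard deviation.
#' @slot poissonNoise logical, add Poisson shot noise.
#' @slot tiltMaxDeg maximum out-of-plane fiber tilt (degrees).
#' @slot seed integer RNG seed; identical seed + parameters give
#'   bit-identical phantoms.
#' @exportClass PhantomTruth
setClass("PhantomTruth",
  representation(layerThicknessMm = "numeric", boundaryUndulationMm = "numeric",
                 undulationPeriods = "numeric", fiberAnglesDeg = "numeric",
                 mixtureWeights = "numeric", nFibers = "integer",
                 fiberRadiusUm = "numeric", fiberLengthUm = "numeric",
                 plantedCrossingCount = "integer",
                 intensityScale = "numeric", noiseSigma = "numeric",
                 poissonNoise = "logical", tiltMaxDeg = "numeric",
                 seed = "integer"),
  validity = function(object) {
    w <- object@mixtureWeights
    if (length(w) != 3 || any(w < 0) || abs(sum(w) - 1) > 1e-9)
      return("mixtureWeights must be 3 non-negative fractions summing to 1")
    a <- object@fiberAnglesDeg
    if (length(a) && (any(a < 0) || any(a >= 180)))
      return("fiberAnglesDeg must lie in [0, 180)")
    if (!is.na(object@plantedCrossingCount) && object@plantedCrossingCount < 0)
      return("plantedCrossingCount must be >= 0")
    if (any(object@layerThicknessMm < 0))
      return("layer thicknesses must be non-negative")
    if (object@fiberRadiusUm <= 0) return("fiberRadiusUm must be positive")
    if (!is.na(object@fiberLengthUm) && object@fiberLengthUm <= 0)
      return("fiberLengthUm must be positive (or NA for full-field fibers)")
    if (object@boundaryUndulationMm < 0)
      return("boundaryUndulationMm must be non-negative")
    TRUE
  })

#' Construct phantom ground truth
#'
#' Defaults describe a proximal-trunk-like site: layer thicknesses from the
#' dorsal 3 cm reference row (SC 0.39, VE 0.05, D 0.8 mm), a balanced
#' bimodal angle mixture (25\% perpendicular, 25\% parallel, 50\% diffuse),
#' 10 um thick fibers, a 12-bit intensity scale of 600 with Gaussian read
#' noise at 5\% of that scale.
#'
#' @param layerThicknessMm named numeric (SC, VE, D), mm.
#' @param boundaryUndulationMm sinusoidal boundary amplitude, mm.
#' @param undulationPeriods full periods across the image width.
#' @param mixtureWeights fractions (perpendicular, parallel, diffuse).
#' @param nFibers number of fibers.
#' @param fiberAnglesDeg optional explicit angle list (else drawn from the
#'   mixture at generation time).
#' @param fiberRadiusUm fiber tube radius, um.
#' @param fiberLengthUm fiber length, um (\code{NA}: full-field chords).
#' @param plantedCrossingCount crossings to plant (\code{NA}: unconstrained).
#' @param intensityScale mean on-fiber intensity, arbitrary units.
#' @param noiseSigma Gaussian noise sd (default 5\% of intensityScale).
#' @param poissonNoise add Poisson shot noise.
#' @param tiltMaxDeg maximum out-of-plane tilt, degrees.
#' @param seed integer seed.
#' @return A \code{PhantomTruth} object.
#' @export
phantomTruth <- function(layerThicknessMm = c(SC = 0.39, VE = 0.05, D = 0.8),
                         boundaryUndulationMm = 0.15,
                         undulationPeriods = 4,
                         mixtureWeights = c(perpendicular = 0.25,
                                            parallel = 0.25, diffuse = 0.5),
                         nFibers = 200L,
                         fiberAnglesDeg = numeric(0),
                         fiberRadiusUm = 5,
                         fiberLengthUm = NA_real_,
                         plantedCrossingCount = NA_integer_,
                         intensityScale = 600,
                         noiseSigma = 0.05 * intensityScale,
                         poissonNoise = FALSE,
                         tiltMaxDeg = 10,
                         seed = 1L) {
  lt <- layerThicknessMm
  if (is.null(names(lt))) names(lt) <- LAYER_NAMES[seq_along(lt)]
  miss <- setdiff(LAYER_NAMES, names(lt))
  lt[miss] <- 0
  lt <- lt[LAYER_NAMES]
  mw <- mixtureWeights
  if (is.null(names(mw))) names(mw) <- MIXTURE_NAMES
  new("PhantomTruth", layerThicknessMm = lt,
      boundaryUndulationMm = boundaryUndulationMm,
      undulationPeriods = undulationPeriods,
      fiberAnglesDeg = as.numeric(fiberAnglesDeg),
      mixtureWeights = mw[MIXTURE_NAMES], nFibers = as.integer(nFibers),
      fiberRadiusUm = fiberRadiusUm, fiberLengthUm = as.numeric(fiberLengthUm),
      plantedCrossingCount = as.integer(plantedCrossingCount),
      intensityScale = intensityScale, noiseSigma = noiseSigma,
      poissonNoise = poissonNoise, tiltMaxDeg = tiltMaxDeg,
      seed = as.integer(seed))
}

#' Labeled histology section
#'
#' A 2D integer label image (0 background, 1 stratum corneum, 2 viable
#' epidermis, 3 dermis) with its physical pixel size. Rows run along the
#' skin's outward normal by convention; \code{normalAxis} records which image
#' axis that is.
#'
#' @slot labels integer matrix with values in \{0, 1, 2, 3\}.
#' @slot pixelSizeMm physical pixel size, mm.
#' @slot normalAxis "y" (rows, default) or "x" (columns).
#' @slot meta a \code{SampleMeta}.
#' @exportClass LayerImage
setClass("LayerImage",
  representation(labels = "matrix", pixelSizeMm = "numeric",
                 normalAxis = "character", meta = "SampleMeta"),
  validity = function(object) {
    if (!all(object@labels %in% 0:3)) {
      bad <- setdiff(unique(as.vector(object@labels)), 0:3)
      return(sprintf("unknown label value(s): %s",
                     paste(bad, collapse = ", ")))
    }
    if (object@pixelSizeMm <= 0) return("pixelSizeMm must be positive")
    if (!object@normalAxis %in% c("y", "x"))
      return("normalAxis must be 'y' or 'x'")
    TRUE
  })

#' Construct a LayerImage
#'
#' @param labels integer matrix of layer codes (0 = background, 1 = SC,
#'   2 = VE, 3 = D).
#' @param pixelSizeMm pixel size in mm.
#' @param normalAxis image axis along the outward skin normal ("y" rows).
#' @param meta a \code{SampleMeta}.
#' @return A \code{LayerImage}.
#' @export
layerImage <- function(labels, pixelSizeMm, normalAxis = "y",
                       meta = sampleMeta()) {
  storage.mode(labels) <- "integer"
  new("LayerImage", labels = labels, pixelSizeMm = pixelSizeMm,
      normalAxis = normalAxis, meta = meta)
}

#' SHG intensity stack
#'
#' A 3D single-channel intensity array (dimensions y, x, z) with physical
#' voxel sizes in micrometres, the in-plane axis that points along the skin's
#' outward normal, sample metadata, and an ordered log of the processing
#' operations applied so far.
#'
#' @slot intensities non-negative 3D numeric array, dim (y, x, z).
#' @slot voxelUm named numeric (y, x, z), um per voxel.
#' @slot normalAxis "y" (default) or "x".
#' @slot meta a \code{SampleMeta}.
#' @slot processingLog list of applied operations with their parameters.
#' @exportClass ShgStack
setClass("ShgStack",
  representation(intensities = "array", voxelUm = "numeric",
                 normalAxis = "character", meta = "SampleMeta",
                 processingLog = "list"),
  validity = function(object) {
    if (length(dim(object@intensities)) != 3)
      return("intensities must be a 3D array (y, x, z)")
    if (any(object@intensities < 0, na.rm = TRUE))
      return("intensities must be non-negative")
    if (length(object@voxelUm) != 3 || any(object@voxelUm <= 0))
      return("voxelUm must be 3 positive sizes (y, x, z)")
    if (!object@normalAxis %in% c("y", "x"))
      return("normalAxis must be 'y' or 'x'")
    TRUE
  })

#' Construct an ShgStack
#'
#' @param intensities 3D array (y, x, z) or a matrix (promoted to one slice).
#' @param voxelUm voxel sizes in um, order (y, x, z). Defaults to the
#'   acquisition geometry of 1.21 um in-plane and a 10.62 um z step.
#' @param normalAxis in-plane axis of the outward skin normal.
#' @param meta a \code{SampleMeta}.
#' @param processingLog prior processing log entries.
#' @return An \code{ShgStack}.
#' @export
shgStack <- function(intensities, voxelUm = c(y = 1.21, x = 1.21, z = 10.62),
                     normalAxis = "y", meta = sampleMeta(),
                     processingLog = list()) {
  if (is.matrix(intensities))
    intensities <- array(intensities, dim = c(dim(intensities), 1L))
  v <- voxelUm
  if (is.null(names(v))) names(v) <- c("y", "x", "z")
  new("ShgStack", intensities = intensities, voxelUm = v[c("y", "x", "z")],
      normalAxis = normalAxis, meta = meta, processingLog = processingLog)
}

#' Traced fiber set
#'
#' Fibers as polylines in physical micrometre coordinates (columns y, x, z),
#' with a representative in-plane angle per fiber (degrees from the outward
#' normal, in [0, 180)), a salience (mean ridge response along the trace),
#' and a tube radius estimate.
#'
#' @slot fibers list of numeric matrices, each n x 3 (y, x, z in um), n >= 2.
#' @slot angleDeg numeric, per-fiber angle in [0, 180).
#' @slot salience numeric, per-fiber non-negative salience.
#' @slot radiusUm numeric, per-fiber radius in um.
#' @exportClass FiberSet
setClass("FiberSet",
  representation(fibers = "list", angleDeg = "numeric", salience = "numeric",
                 radiusUm = "numeric"),
  validity = function(object) {
    n <- length(object@fibers)
    if (length(object@angleDeg) != n || length(object@salience) != n ||
        length(object@radiusUm) != n)
      return("per-fiber vectors must match the number of fibers")
    if (n) {
      if (any(vapply(object@fibers, nrow, 1L) < 2))
        return("every polyline needs >= 2 points")
      if (any(object@angleDeg < 0 | object@angleDeg >= 180))
        return("angles must lie in [0, 180)")
      if (any(object@salience < 0, na.rm = TRUE))
        return("salience must be non-negative")
    }
    TRUE
  })

#' Construct a FiberSet
#'
#' @param fibers list of n x 3 matrices (y, x, z in um).
#' @param angleDeg per-fiber in-plane angle from the outward normal,
#'   degrees in [0, 180). Computed from the polylines when missing.
#' @param salience per-fiber salience (default 1).
#' @param radiusUm per-fiber radius in um (default \code{NA}).
#' @return A \code{FiberSet}.
#' @export
fiberSet <- function(fibers, angleDeg = NULL, salience = NULL,
                     radiusUm = NULL) {
  fibers <- lapply(fibers, function(p) {
    p <- as.matrix(p)
    if (ncol(p) == 2) p <- cbind(p, 0)
    colnames(p) <- c("y", "x", "z")
    p
  })
  n <- length(fibers)
  if (is.null(angleDeg)) angleDeg <- vapply(fibers, polylineAngle, 1.0)
  if (is.null(salience)) salience <- rep(1, n)
  if (is.null(radiusUm)) radiusUm <- rep(NA_real_, n)
  if (length(radiusUm) == 1L && n > 1L) radiusUm <- rep(radiusUm, n)
  new("FiberSet", fibers = fibers, angleDeg = as.numeric(angleDeg),
      salience = as.numeric(salience), radiusUm = as.numeric(radiusUm))
}

#' Per-strip layer thickness profile
#'
#' One thickness value per one-pixel-wide strip (image column) and per layer,
#' in mm, with the site metadata needed for tabulation.
#'
#' @slot perStripMm named list (SC, VE, D) of per-strip thicknesses, mm.
#' @slot pixelSizeMm pixel size used, mm.
#' @slot meta a \code{SampleMeta}.
#' @exportClass ThicknessProfile
setClass("ThicknessProfile",
  representation(perStripMm = "list", pixelSizeMm = "numeric",
                 meta = "SampleMeta"),
  validity = function(object) {
    if (!identical(sort(names(object@perStripMm)), sort(LAYER_NAMES)))
      return("perStripMm must have entries SC, VE, D")
    len <- vapply(object@perStripMm, length, 1L)
    if (length(unique(len)) != 1)
      return("per-strip vectors must share one length (the image width)")
    if (any(unlist(object@perStripMm) < 0))
      return("thicknesses must be non-negative")
    TRUE
  })

#' ROI intensity summary
#'
#' Mean SHG intensity per region of interest plus the grand mean and sd over
#' ROIs, in arbitrary units.
#'
#' @slot perRoiMean numeric mean intensity per ROI.
#' @slot grandMean mean of \code{perRoiMean}.
#' @slot grandSd sd of \code{perRoiMean} (0 for a single ROI).
#' @slot units character unit label (arbitrary units by default).
#' @slot meta a \code{SampleMeta}.
#' @exportClass IntensityResult
setClass("IntensityResult",
  representation(perRoiMean = "numeric", grandMean = "numeric",
                 grandSd = "numeric", units = "character",
                 meta = "SampleMeta"),
  validity = function(object) {
    if (length(object@perRoiMean) &&
        abs(object@grandMean - mean(object@perRoiMean)) > 1e-8 *
          max(1, abs(object@grandMean)))
      return("grandMean must equal mean(perRoiMean)")
    TRUE
  })

#' Angular orientation summary
#'
#' Angular histogram plus the percentage of fibers in the perpendicular
#' (0 +- hw and 180 -+ hw degrees) and parallel (90 +- hw) windows, and the
#' bimodality call (both percentages >= 20).
#'
#' @slot histogram named numeric bin counts (bins of \code{binWidthDeg}).
#' @slot binWidthDeg histogram bin width, degrees.
#' @slot pctPerpendicular percentage in the perpendicular window (NA if no
#'   fibers).
#' @slot pctParallel percentage in the parallel window (NA if no fibers).
#' @slot nFibers number of fibers summarized.
#' @slot bimodal logical; NA when no fibers.
#' @exportClass OrientationSummary
setClass("OrientationSummary",
  representation(histogram = "numeric", binWidthDeg = "numeric",
                 pctPerpendicular = "numeric", pctParallel = "numeric",
                 nFibers = "integer", bimodal = "logical"),
  validity = function(object) {
    if (object@nFibers > 0) {
      p1 <- object@pctPerpendicular; p2 <- object@pctParallel
      if (p1 < 0 || p1 > 100 || p2 < 0 || p2 > 100)
        return("percentages must lie in [0, 100]")
      if (p1 + p2 > 100 + 1e-9)
        return("window percentages cannot exceed 100 in total")
      if (abs(sum(object@histogram) - object@nFibers) > 1e-9)
        return("histogram counts must sum to nFibers")
    }
    TRUE
  })

#' Fiber crossing result
#'
#' Crossing count, locations, the ROI volume (when restricted to one) and
#' the crossing density per cubic micrometre.
#'
#' @slot crossingCount integer number of crossings.
#' @slot crossingLocations n x 3 matrix of (y, x, z) um.
#' @slot pairIds n x 2 matrix of the crossing fiber indices.
#' @slot roiVolumeUm3 ROI volume in um^3 (NA when unrestricted).
#' @slot densityPerUm3 crossings per um^3 (NA when unrestricted).
#' @exportClass CrossingResult
setClass("CrossingResult",
  representation(crossingCount = "integer", crossingLocations = "matrix",
                 pairIds = "matrix", roiVolumeUm3 = "numeric",
                 densityPerUm3 = "numeric"),
  validity = function(object) {
    if (nrow(object@crossingLocations) != object@crossingCount)
      return("crossingCount must equal the number of locations")
    if (!is.na(object@roiVolumeUm3)) {
      if (object@roiVolumeUm3 <= 0) return("roiVolumeUm3 must be positive")
      if (abs(object@densityPerUm3 -
              object@crossingCount / object@roiVolumeUm3) > 1e-12)
        return("density must equal count / volume")
    }
    TRUE
  })

#' Two-group comparison result
#'
#' A two-sample t-test with Shapiro-Wilk normality and Levene variance
#' diagnostics, following the study's statistical recipe: the t-test is
#' always reported (Welch variant when Levene rejects homogeneity), the
#' diagnostics are recorded alongside.
#'
#' @slot testName character, test performed.
#' @slot statistic t statistic.
#' @slot pValue two-sided p-value.
#' @slot nPerGroup integer sample sizes.
#' @slot groupMeans,groupSds per-group mean and sd.
#' @slot normalityOk logical per group (Shapiro-Wilk p > 0.05).
#' @slot varianceHomogeneous logical (Levene p > 0.05).
#' @slot stars significance label: "ns", "*", "**" or "***".
#' @exportClass StatResult
setClass("StatResult",
  representation(testName = "character", statistic = "numeric",
                 pValue = "numeric", nPerGroup = "integer",
                 groupMeans = "numeric", groupSds = "numeric",
                 normalityOk = "logical", varianceHomogeneous = "logical",
                 stars = "character"),
  validity = function(object) {
    if (!is.na(object@pValue) &&
        (object@pValue < 0 || object@pValue > 1))
      return("pValue must lie in [0, 1]")
    if (!object@stars %in% c("ns", "*", "**", "***"))
      return("stars must be one of ns, *, **, ***")
    TRUE
  })
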