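# SHG stack preprocessing: intensity clipping, small-sigma Gaussian blur and
# rolling-ball background subtraction, applied per slice (the z step is ~9x
# the in-plane pixel, so slices are treated as independent 2D images).
# Arithmetic stays in floating point; quantization happens only on export.

#' Clip stack intensities to a display range
#'
#' Values below \code{lo} are set to \code{lo} and values above \code{hi} to
#' \code{hi}; everything else is unchanged.
#'
#' @param x an \code{ShgStack} or numeric array/matrix.
#' @param lo,hi clip bounds, \code{lo < hi}; defaults 0 and 4000.
#' @return Same class as the input, with the operation logged on stacks.
#' @rdname clipRange
#' @export
setMethod("clipRange", "ShgStack", function(x, lo = 0, hi = 4000) {
  x@intensities <- clipRange(x@intensities, lo, hi)
  appendLog(x, "clip_range", list(lo = lo, hi = hi))
})

#' @rdname clipRange
#' @export
setMethod("clipRange", "ANY", function(x, lo = 0, hi = 4000) {
  stopifnot(is.numeric(x), lo < hi)
  pmin(pmax(x, lo), hi)
})

#' Per-slice Gaussian blur
#'
#' Convolves every z slice with a normalized sampled-Gaussian kernel of the
#' given standard deviation (pixels) using reflective boundary handling, so
#' total intensity is conserved for interior-supported images.
#' \code{sigmaPx = 0} is the identity.
#'
#' @param x an \code{ShgStack} or numeric matrix/3D array.
#' @param sigmaPx Gaussian sd in pixels, >= 0; default 0.5.
#' @return Same class as the input.
#' @rdname gaussianBlur
#' @export
setMethod("gaussianBlur", "ShgStack", function(x, sigmaPx = 0.5) {
  x@intensities <- gaussianBlur(x@intensities, sigmaPx)
  appendLog(x, "gaussian_blur", list(sigma_px = sigmaPx))
})

#' @rdname gaussianBlur
#' @export
setMethod("gaussianBlur", "ANY", function(x, sigmaPx = 0.5) {
  stopifnot(is.numeric(x))
  if (sigmaPx < 0) stop("sigmaPx must be non-negative")
  if (sigmaPx == 0) return(x)
  k <- gaussKernel(sigmaPx)
  if (is.matrix(x)) return(cpp_sep_conv(x, k, k))
  slicesToStack(lapply(stackSlices(x), cpp_sep_conv, ky = k, kx = k))
})

# Spherical-cap structuring function of the given pixel radius: heights
# sqrt(r^2 - d^2) - r (in [-r, 0]) inside the support, NA outside.
ballElement <- function(radiusPx) {
  r <- radiusPx
  off <- seq(-floor(r), floor(r))
  d2 <- outer(off^2, off^2, "+")
  h <- ifelse(d2 <= r^2, sqrt(pmax(r^2 - d2, 0)) - r, NA_real_)
  h
}

#' Rolling-ball background subtraction
#'
#' The background of each slice is its grayscale opening by an exact
#' spherical-cap structuring element of the stated radius (erosion followed
#' by dilation with the ball's height profile); the output is the slice minus
#' that background, floored at zero. The opening is anti-extensive, so the
#' output never exceeds the input, and idempotent, so re-estimating the
#' background of a background gives it back.
#'
#' @param x an \code{ShgStack} or numeric matrix/3D array.
#' @param radiusPx ball radius in pixels, >= 1; default 40.
#' @return Same class as the input.
#' @rdname rollingBallSubtract
#' @export
setMethod("rollingBallSubtract", "ShgStack", function(x, radiusPx = 40) {
  x@intensities <- rollingBallSubtract(x@intensities, radiusPx)
  appendLog(x, "rolling_ball_subtract", list(radius_px = radiusPx))
})

#' @rdname rollingBallSubtract
#' @export
setMethod("rollingBallSubtract", "ANY", function(x, radiusPx = 40) {
  stopifnot(is.numeric(x))
  if (radiusPx < 1) stop("radiusPx must be >= 1")
  worker <- function(m) {
    if (radiusPx > max(dim(m)))
      stop("rolling-ball radius exceeds the slice extent")
    pmax(m - rollingBallBackground(m, radiusPx), 0)
  }
  if (is.matrix(x)) return(worker(x))
  slicesToStack(lapply(stackSlices(x), worker))
})

#' Rolling-ball background estimate of one slice
#'
#' @param m numeric matrix.
#' @param radiusPx ball radius in pixels.
#' @return The grayscale opening of \code{m} by the spherical-cap element.
#' @export
rollingBallBackground <- function(m, radiusPx = 40) {
  se <- ballElement(radiusPx)
  cpp_gray_dilate(cpp_gray_erode(m, se), se)
}

#' Apply the standard preprocessing chain
#'
#' Runs, in order: intensity clipping to (0, 4000), Gaussian blur with
#' sigma 0.5 px, and rolling-ball background subtraction with radius 40 px.
#' Every step is appended to the stack's processing log.
#'
#' @param s an \code{ShgStack}.
#' @param clip numeric length-2 clip bounds.
#' @param sigmaPx blur sd in pixels.
#' @param ballRadiusPx rolling-ball radius in pixels.
#' @return The processed \code{ShgStack}.
#' @export
processStack <- function(s, clip = c(0, 4000), sigmaPx = 0.5,
                         ballRadiusPx = 40) {
  s <- clipRange(s, clip[1], clip[2])
  s <- gaussianBlur(s, sigmaPx)
  rollingBallSubtract(s, ballRadiusPx)
}
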