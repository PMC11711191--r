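# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. NULL/NA seed leaves the RNG untouched.
withSeed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# In-plane angle of a direction (dy, dx), degrees from the +y axis (the
# outward-normal axis), mapped into [0, 180): 0 = along the normal
# (perpendicular fiber), 90 = along the surface (parallel fiber).
directionAngle <- function(dy, dx) {
  a <- atan2(dx, dy) * 180 / pi
  a <- a %% 180
  a[a >= 180] <- 0
  a
}

# Representative angle of a polyline (n x >=2 matrix, columns y, x[, z]) by
# total least squares on the in-plane coordinates: first principal axis of
# the centred (y, x) scatter.
polylineAngle <- function(p) {
  yx <- p[, 1:2, drop = FALSE]
  yx <- sweep(yx, 2, colMeans(yx))
  cv <- crossprod(yx) / max(1, nrow(yx) - 1)
  e <- eigen(cv, symmetric = TRUE)
  v <- e$vectors[, 1]
  directionAngle(v[1], v[2])
}

# Smallest circular difference between two undirected orientations (deg).
angleDiff180 <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

polylineLength <- function(p) {
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] -
                    p[-nrow(p), , drop = FALSE])^2)))
}

# Normalized sampled-Gaussian kernel of standard deviation sigma (pixels).
gaussKernel <- function(sigma, radius = max(1L, ceiling(4 * sigma))) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Sampled Gaussian derivative kernels used by the ridge filter. These are
# deliberately un-normalized samples of the analytic derivatives; the ridge
# response is only compared against itself so absolute scale cancels.
gaussDerivKernel <- function(sigma, order, radius = max(1L, ceiling(4 * sigma))) {
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
         "0" = g,
         "1" = -x / sigma^2 * g,
         "2" = (x^2 / sigma^4 - 1 / sigma^2) * g,
         stop("unsupported derivative order"))
}

stackSlices <- function(x) {
  lapply(seq_len(dim(x)[3]), function(k) x[, , k, drop = TRUE])
}

slicesToStack <- function(slices) {
  array(unlist(slices, use.names = FALSE),
        dim = c(dim(slices[[1]]), length(slices)))
}

appendLog <- function(s, op, params) {
  s@processingLog <- c(s@processingLog, list(c(list(op = op), params)))
  s
}

# Crop an ShgStack in-plane (1-based pixel indices, all z retained).
cropStack <- function(s, y0, x0, h, w) {
  d <- dim(s@intensities)
  if (y0 < 1 || x0 < 1 || y0 + h - 1 > d[1] || x0 + w - 1 > d[2])
    stop("crop window lies outside the stack")
  out <- s
  out@intensities <- s@intensities[y0:(y0 + h - 1), x0:(x0 + w - 1), ,
                                   drop = FALSE]
  appendLog(out, "crop", list(y0 = y0, x0 = x0, h = h, w = w))
}

# Rotate a stack by 90 degrees in-plane (x' = y, y' = nx + 1 - x), mapping a
# fiber at angle theta to theta + 90 (mod 180).
rotateStack90 <- function(s) {
  rot <- apply(s@intensities, 3, function(m) t(m)[, rev(seq_len(nrow(m))),
                                                  drop = FALSE])
  d <- dim(s@intensities)
  out <- s
  out@intensities <- array(rot, dim = c(d[2], d[1], d[3]))
  out@voxelUm <- s@voxelUm[c("x", "y", "z")]
  names(out@voxelUm) <- c("y", "x", "z")
  appendLog(out, "rotate90", list())
}
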