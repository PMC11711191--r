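# ROI-based SHG intensity quantification: ten randomly placed regions of
# interest of 200 x 250 um, at least 150 px from the image boundary, averaged
# (the dorsal-vs-ventral intensity comparison logic).

#' Sample non-overlapping rectangular ROIs
#'
#' Places \code{n} regions of interest of the given physical size uniformly
#' at random inside the admissible area (the image minus a pixel margin on
#' every side), rejecting overlapping candidates. Placement is deterministic
#' given \code{seed}. ROIs are in-plane; the same specs apply to every slice
#' or to a projection.
#'
#' @param s an \code{ShgStack}.
#' @param n number of ROIs (default 10).
#' @param sizeUm ROI size (y, x) in um; default 200 x 250.
#' @param marginPx minimum distance from the image boundary, pixels.
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @param nonOverlapping enforce pairwise disjoint ROIs (default TRUE).
#' @param maxTries rejection-sampling budget.
#' @return data.frame with one row per ROI: roi, y0, x0, h, w (pixels,
#'   1-based origin).
#' @export
sampleRois <- function(s, n = 10L, sizeUm = c(200, 250), marginPx = 150L,
                       seed = NULL, nonOverlapping = TRUE,
                       maxTries = 5000L) {
  d <- dim(s@intensities)
  v <- s@voxelUm
  h <- max(1L, as.integer(round(sizeUm[1] / v["y"])))
  w <- max(1L, as.integer(round(sizeUm[2] / v["x"])))
  empty <- data.frame(roi = integer(0), y0 = integer(0), x0 = integer(0),
                      h = integer(0), w = integer(0))
  if (n == 0) return(empty)
  yMax <- d[1] - marginPx - h + 1L
  xMax <- d[2] - marginPx - w + 1L
  yMin <- marginPx + 1L
  xMin <- marginPx + 1L
  if (yMax < yMin || xMax < xMin)
    stop(sprintf(
      "no admissible ROI placement: %d x %d px ROI with %d px margin does not fit a %d x %d image (max feasible n = 0)",
      h, w, marginPx, d[1], d[2]))
  withSeed(seed, {
    # dart throwing with restarts: a failed packing is abandoned entirely,
    # which escapes the dead ends sequential rejection runs into when the
    # ROIs are large relative to the admissible region
    best <- 0L
    acc <- NULL
    for (restart in seq_len(60L)) {
      acc <- matrix(0L, nrow = 0, ncol = 2)
      tries <- 0L
      while (nrow(acc) < n && tries < maxTries %/% 10L) {
        tries <- tries + 1L
        y0 <- sample.int(yMax - yMin + 1L, 1L) + yMin - 1L
        x0 <- sample.int(xMax - xMin + 1L, 1L) + xMin - 1L
        if (nonOverlapping && nrow(acc)) {
          clash <- any(abs(acc[, 1] - y0) < h & abs(acc[, 2] - x0) < w)
          if (clash) next
        }
        acc <- rbind(acc, c(y0, x0))
      }
      best <- max(best, nrow(acc))
      if (nrow(acc) == n) break
    }
    if (nrow(acc) < n)
      stop(sprintf(
        "could only place %d of %d non-overlapping ROIs within the sampling budget",
        best, n))
    data.frame(roi = seq_len(n), y0 = acc[, 1], x0 = acc[, 2],
               h = h, w = w)
  })
}

#' Mean intensity per ROI
#'
#' Computes the arithmetic mean intensity inside each ROI, by default on the
#' maximum-intensity z projection (matching stacked-image figures), or over
#' the full 3D box when \code{project = FALSE}.
#'
#' @param s an \code{ShgStack}.
#' @param rois data.frame from \code{\link{sampleRois}}.
#' @param project use the max-intensity z projection (default TRUE).
#' @return An \code{IntensityResult}.
#' @export
roiMeanIntensity <- function(s, rois, project = TRUE) {
  d <- dim(s@intensities)
  img <- if (project) Reduce(pmax, stackSlices(s@intensities)) else NULL
  per <- vapply(seq_len(nrow(rois)), function(i) {
    y0 <- rois$y0[i]; x0 <- rois$x0[i]; h <- rois$h[i]; w <- rois$w[i]
    if (y0 < 1 || x0 < 1 || y0 + h - 1 > d[1] || x0 + w - 1 > d[2])
      stop(sprintf("ROI %d lies outside the image", rois$roi[i]))
    if (project) mean(img[y0:(y0 + h - 1), x0:(x0 + w - 1)])
    else mean(s@intensities[y0:(y0 + h - 1), x0:(x0 + w - 1), ])
  }, 1.0)
  new("IntensityResult", perRoiMean = per,
      grandMean = if (length(per)) mean(per) else NA_real_,
      grandSd = if (length(per) > 1) stats::sd(per) else 0,
      units = "a.u.", meta = s@meta)
}

#' Contrast two intensity results
#'
#' Fold-change of the grand means (a over b) plus a two-sample comparison of
#' the per-ROI means (Shapiro-Wilk and Levene diagnostics, then a t-test).
#'
#' @param a,b \code{IntensityResult} objects (e.g. ventral and dorsal).
#' @return list with \code{fold}, \code{test} (a \code{StatResult}) and the
#'   two grand means.
#' @export
intensityContrast <- function(a, b) {
  if (!length(a@perRoiMean) || !length(b@perRoiMean))
    stop("both intensity results must contain at least one ROI")
  if (!identical(a@units, b@units))
    stop(sprintf("unit mismatch: '%s' vs '%s'", a@units, b@units))
  if (b@grandMean == 0)
    stop("undefined ratio: denominator grand mean is zero")
  fold <- a@grandMean / b@grandMean
  test <- compareGroups(a@perRoiMean, b@perRoiMean)
  list(fold = fold, test = test, meanA = a@grandMean, meanB = b@grandMean)
}
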