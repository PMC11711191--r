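#' Draw fiber angles from the angular mixture
#'
#' Mixture components: perpendicular mode (uniform over 0 +- hw and
#' 180 -+ hw degrees), parallel mode (uniform over 90 +- hw), and a diffuse
#' component uniform over the remaining angles.
#'
#' @param n number of angles.
#' @param weights fractions (perpendicular, parallel, diffuse), summing to 1.
#' @param perpHalfwidthDeg,parHalfwidthDeg window half-widths, degrees.
#' @return Numeric angles in [0, 180).
#' @export
sampleMixtureAngles <- function(n, weights = c(0.25, 0.25, 0.5),
                                perpHalfwidthDeg = 5, parHalfwidthDeg = 5) {
  stopifnot(length(weights) == 3, all(weights >= 0),
            abs(sum(weights) - 1) < 1e-9)
  comp <- sample.int(3L, n, replace = TRUE, prob = weights)
  a <- numeric(n)
  iP <- comp == 1L
  a[iP] <- stats::runif(sum(iP), -perpHalfwidthDeg, perpHalfwidthDeg) %% 180
  iQ <- comp == 2L
  a[iQ] <- stats::runif(sum(iQ), 90 - parHalfwidthDeg, 90 + parHalfwidthDeg)
  iD <- comp == 3L
  nD <- sum(iD)
  if (nD) {
    lo1 <- perpHalfwidthDeg; hi1 <- 90 - parHalfwidthDeg
    lo2 <- 90 + parHalfwidthDeg; hi2 <- 180 - perpHalfwidthDeg
    w1 <- hi1 - lo1; w2 <- hi2 - lo2
    side <- stats::runif(nD) < w1 / (w1 + w2)
    a[iD] <- ifelse(side, stats::runif(nD, lo1, hi1),
                    stats::runif(nD, lo2, hi2))
  }
  a
}

#' Generate a layered histology-mask phantom
#'
#' Builds a labeled section with contiguous stratum corneum, viable epidermis
#' and dermis runs in every column (top to bottom: background, SC, VE, D,
#' background). Each layer boundary is perturbed by a sinusoid of amplitude
#' \code{boundaryUndulationMm} with an integer number of periods across the
#' width and a seeded random phase, so per-column thicknesses average to the
#' requested means up to pixel rounding.
#'
#' @param truth a \code{PhantomTruth} (layer thicknesses, undulation, seed).
#' @param widthPx image width in pixels (one strip per column).
#' @param pixelSizeMm physical pixel size, mm.
#' @param heightPx optional image height; computed to fit when missing.
#' @param meta a \code{SampleMeta} for the emitted image.
#' @return A \code{LayerImage}.
#' @examples
#' img <- genLayerImage(phantomTruth(boundaryUndulationMm = 0), 100, 0.01)
#' @export
genLayerImage <- function(truth, widthPx = 1000L, pixelSizeMm = 0.01,
                          heightPx = NULL, meta = sampleMeta()) {
  stopifnot(widthPx >= 10, pixelSizeMm > 0)
  Tm <- truth@layerThicknessMm
  A <- truth@boundaryUndulationMm
  P <- truth@undulationPeriods
  withSeed(truth@seed, {
    phase <- stats::runif(4L, 0, 2 * pi)
    x <- seq_len(widthPx)
    carrier <- 2 * pi * P * (x - 1) / widthPx
    thickPx <- sapply(seq_along(LAYER_NAMES), function(i) {
      Ti <- Tm[[LAYER_NAMES[i]]]
      if (Ti <= 0) return(rep(0L, widthPx))
      t_mm <- pmax(0, Ti + A * sin(carrier + phase[i + 1]))
      as.integer(round(t_mm / pixelSizeMm))
    })
    marginTop <- as.integer(ceiling(A / pixelSizeMm)) + 2L
    top <- marginTop + as.integer(round(A / pixelSizeMm *
                                          sin(carrier + phase[1])))
    total <- rowSums(thickPx)
    need <- max(top + total) + marginTop
    if (is.null(heightPx)) heightPx <- need
    if (heightPx < need) {
      worst <- LAYER_NAMES[which.max(apply(thickPx, 2, max))]
      stop(sprintf(
        "requested thicknesses do not fit a %d px tall image (need %d px); largest layer is %s",
        heightPx, need, worst))
    }
    lab <- matrix(0L, nrow = heightPx, ncol = widthPx)
    for (j in x) {
      r <- top[j]
      for (i in seq_along(LAYER_NAMES)) {
        n <- thickPx[j, i]
        if (n > 0) {
          lab[(r + 1):(r + n), j] <- i
          r <- r + n
        }
      }
    }
    layerImage(lab, pixelSizeMm, meta = meta)
  })
}

# Clip the 3D line p + t*d to the box [0,L] per axis; returns the two
# endpoints as rows of a 2 x 3 matrix, or NULL if the chord is empty.
.clipLineToBox <- function(p, d, L) {
  tmin <- -Inf; tmax <- Inf
  for (k in 1:3) {
    if (abs(d[k]) < 1e-12) {
      if (p[k] < 0 || p[k] > L[k]) return(NULL)
    } else {
      tt <- sort(c((0 - p[k]) / d[k], (L[k] - p[k]) / d[k]))
      tmin <- max(tmin, tt[1]); tmax <- min(tmax, tt[2])
    }
  }
  if (tmax <= tmin) return(NULL)
  rbind(p + tmin * d, p + tmax * d)
}

# One straight fiber through `point` (y, x, z um) with in-plane angle theta
# (deg from +y) and out-of-plane tilt phi (deg), clipped to the box and,
# when lengthUm is finite, to that length centred on the anchor point.
.makeFiber <- function(point, thetaDeg, tiltDeg, extentUm,
                       lengthUm = NA_real_) {
  th <- thetaDeg * pi / 180; ph <- tiltDeg * pi / 180
  d <- c(cos(th) * cos(ph), sin(th) * cos(ph), sin(ph))
  seg <- .clipLineToBox(point, d, extentUm)
  if (is.null(seg) || is.na(lengthUm)) return(seg)
  # arclength positions of the clipped endpoints relative to the anchor
  t1 <- sum((seg[1, ] - point) * d)
  t2 <- sum((seg[2, ] - point) * d)
  lo <- max(t1, -lengthUm / 2)
  hi <- min(t2, lengthUm / 2)
  if (hi <= lo) return(NULL)
  rbind(point + lo * d, point + hi * d)
}

# Do two straight fibers form a crossing under the generator's rule
# (closest approach within dmax, in-plane tangent angle >= minAngle)?
.segmentsCross <- function(a, b, dmax, minAngleDeg) {
  ev <- cpp_polyline_contacts(a, b, dmax)
  if (nrow(ev) == 0) return(FALSE)
  any(angleDiff180(ev[, "ang_a"], ev[, "ang_b"]) >= minAngleDeg)
}

# Place the fiber geometry for a fibrous phantom. Returns list(fibers
# (FiberSet), anglesDeg, crossingCount). Must run inside withSeed().
# Rejection sampling uses a clearance margin beyond the crossing rule
# (distance + angle) so the emitted truth is unambiguous: no fiber pair
# sits on the contact-distance or transversality boundary where estimation
# noise could flip its crossing status.
.genFiberGeometry <- function(truth, extentUm, sliceZUm,
                              minCrossAngleDeg = 15,
                              plantAngleMinDeg = 30,
                              clearanceUm = truth@fiberRadiusUm,
                              clearanceDeg = 5,
                              retryBudget = 200L) {
  n <- truth@nFibers
  r <- truth@fiberRadiusUm
  contact <- 2 * r
  angles <- if (length(truth@fiberAnglesDeg) == n) truth@fiberAnglesDeg
            else sampleMixtureAngles(n, truth@mixtureWeights)
  cplant <- truth@plantedCrossingCount
  constrained <- !is.na(cplant)
  if (constrained && 2L * cplant > n)
    stop(sprintf("cannot plant %d crossings with only %d fibers", cplant, n))
  core <- function() c(stats::runif(1, 0.2 * extentUm[1], 0.8 * extentUm[1]),
                       stats::runif(1, 0.2 * extentUm[2], 0.8 * extentUm[2]))
  segs <- vector("list", n)
  used <- 0L
  if (constrained && cplant > 0) {
    for (k in seq_len(cplant)) {
      ok <- FALSE
      for (try in seq_len(retryBudget)) {
        z <- sliceZUm[sample.int(length(sliceZUm), 1L)]
        p <- c(core(), z)
        th1 <- angles[used + 1L]
        th2 <- angles[used + 2L]
        tries2 <- 0L
        while (angleDiff180(th1, th2) < plantAngleMinDeg && tries2 < 100L) {
          th2 <- sampleMixtureAngles(1L, truth@mixtureWeights)
          tries2 <- tries2 + 1L
        }
        if (angleDiff180(th1, th2) < plantAngleMinDeg)
          th2 <- (th1 + 90) %% 180
        f1 <- .makeFiber(p, th1, 0, extentUm, truth@fiberLengthUm)
        f2 <- .makeFiber(p, th2, 0, extentUm, truth@fiberLengthUm)
        if (is.null(f1) || is.null(f2)) next
        clash <- FALSE
        for (m in seq_len(used)) {
          if (.segmentsCross(segs[[m]], f1, contact + clearanceUm,
                             minCrossAngleDeg - clearanceDeg) ||
              .segmentsCross(segs[[m]], f2, contact + clearanceUm,
                             minCrossAngleDeg - clearanceDeg)) {
            clash <- TRUE; break
          }
        }
        if (!clash) {
          segs[[used + 1L]] <- f1; segs[[used + 2L]] <- f2
          angles[used + 1L] <- th1; angles[used + 2L] <- th2
          used <- used + 2L; ok <- TRUE; break
        }
      }
      if (!ok)
        stop(sprintf(
          "unable to plant crossing %d of %d within the retry budget (%d attempts)",
          k, cplant, retryBudget))
    }
  }
  for (i in seq_len(n - used)) {
    idx <- used + 1L
    placed <- FALSE
    for (try in seq_len(retryBudget)) {
      z <- sliceZUm[sample.int(length(sliceZUm), 1L)]
      p <- c(stats::runif(1, 0, extentUm[1]), stats::runif(1, 0, extentUm[2]), z)
      tilt <- stats::runif(1, -truth@tiltMaxDeg, truth@tiltMaxDeg)
      f <- .makeFiber(p, angles[idx], tilt, extentUm, truth@fiberLengthUm)
      if (is.null(f) || polylineLength(f) < 4 * r) next
      if (constrained) {
        clash <- FALSE
        for (m in seq_len(used)) {
          if (.segmentsCross(segs[[m]], f, contact + clearanceUm,
                             minCrossAngleDeg - clearanceDeg)) {
            clash <- TRUE; break
          }
        }
        if (clash) next
      }
      segs[[idx]] <- f
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf(
        "unable to place fiber %d without incidental crossings within the retry budget",
        idx))
    used <- used + 1L
  }
  # realized crossing count under the generator's geometric rule
  K <- 0L
  if (n > 1) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (.segmentsCross(segs[[i]], segs[[j]], contact, minCrossAngleDeg))
        K <- K + 1L
    }
  }
  fs <- fiberSet(segs, angleDeg = angles, salience = rep(1, n),
                 radiusUm = rep(r, n))
  list(fibers = fs, anglesDeg = angles, crossingCount = K)
}

#' Render a fiber set as a binary tube mask
#'
#' Draws each polyline as a constant-radius tube into a voxel grid whose
#' voxel centres sit at (i - 1) * voxel size along each axis.
#'
#' @param f a \code{FiberSet} with radii (or supply \code{radiusUm}).
#' @param shapePx integer (y, x, z) grid size.
#' @param voxelUm voxel sizes (y, x, z) in um.
#' @param radiusUm optional radius override applied to all fibers.
#' @return A 3D 0/1 integer array of dim \code{shapePx}.
#' @export
renderFiberSet <- function(f, shapePx, voxelUm = c(y = 1.21, x = 1.21,
                                                   z = 10.62),
                           radiusUm = NULL) {
  segs <- do.call(rbind, lapply(seq_along(f@fibers), function(i) {
    p <- f@fibers[[i]]
    r <- if (!is.null(radiusUm)) radiusUm else f@radiusUm[i]
    if (is.na(r)) stop("fiber radius missing; supply radiusUm")
    k <- nrow(p)
    cbind(p[-k, 1], p[-k, 2], p[-k, 3], p[-1, 1], p[-1, 2], p[-1, 3], r)
  }))
  if (is.null(segs))
    return(array(0L, dim = as.integer(shapePx)))
  cpp_render_tubes(segs, as.integer(shapePx), as.numeric(voxelUm))
}

# Blur in-plane with the generator PSF, add noise, clip to the 12-bit range.
.renderAndCorrupt <- function(mask, scale, voxelUm, psfSigmaUm, noiseSigma,
                              poisson) {
  stack <- scale * mask
  sy <- psfSigmaUm[1] / voxelUm[1]; sx <- psfSigmaUm[2] / voxelUm[2]
  if (sy > 0.05 && sx > 0.05) {
    ky <- gaussKernel(sy); kx <- gaussKernel(sx)
    stack <- slicesToStack(lapply(stackSlices(stack), cpp_sep_conv,
                                  ky = ky, kx = kx))
  }
  clipped <- FALSE
  if (poisson) stack[] <- stats::rpois(length(stack), pmax(stack, 0))
  if (noiseSigma > 0)
    stack <- stack + stats::rnorm(length(stack), 0, noiseSigma)
  if (max(stack) > 4095) clipped <- TRUE
  stack <- pmin(pmax(stack, 0), 4095)
  list(stack = stack, clipped = clipped)
}

#' Generate a fibrous SHG-like stack with known ground truth
#'
#' Places straight fibers (optional bounded out-of-plane tilt) with in-plane
#' angles drawn from the phantom's angular mixture, renders them as 10 um
#' thick tubes, applies the generator point-spread blur and read noise, and
#' returns both the stack and the exact ground-truth \code{FiberSet}. When
#' \code{plantedCrossingCount} is set, fibers are added in transversally
#' intersecting pairs until the count is met, the remaining fibers are
#' rejection-sampled to avoid incidental crossings, and the realized count
#' (including any residual incidental crossings) is written back into the
#' emitted truth.
#'
#' @param truth a \code{PhantomTruth}.
#' @param shapePx integer (y, x, z) stack size in voxels.
#' @param voxelUm voxel sizes (y, x, z), um; defaults to the 1.21 um in-plane
#'   pixel and 10.62 um z step of the acquisition geometry.
#' @param psfSigmaUm generator PSF sigma (y, x, z), um; defaults derived from
#'   bead-calibration FWHM of 315/300/1365 nm.
#' @param meta a \code{SampleMeta}.
#' @param retryBudget placement retries before a generation error.
#' @return \code{list(stack, fibers, truth)} with \code{truth} updated to the
#'   emitted angle list and realized crossing count.
#' @export
genFiberStack <- function(truth, shapePx = c(y = 320L, x = 320L, z = 25L),
                          voxelUm = c(y = 1.21, x = 1.21, z = 10.62),
                          psfSigmaUm = c(y = 0.13, x = 0.13, z = 0.58),
                          meta = sampleMeta(), retryBudget = 200L) {
  shapePx <- as.integer(shapePx)
  extent <- (shapePx - 1L) * voxelUm
  if (min(extent[1:2]) < 4 * truth@fiberRadiusUm)
    stop("stack too small to hold a fiber of the stated radius")
  withSeed(truth@seed, {
    geo <- .genFiberGeometry(truth, extent, sliceZUm = (seq_len(shapePx[3]) - 1) *
                               voxelUm[3], retryBudget = retryBudget)
    mask <- renderFiberSet(geo$fibers, shapePx, voxelUm)
    rc <- .renderAndCorrupt(mask, truth@intensityScale, voxelUm, psfSigmaUm,
                            truth@noiseSigma, truth@poissonNoise)
    truth@fiberAnglesDeg <- geo$anglesDeg
    if (!is.na(truth@plantedCrossingCount))
      truth@plantedCrossingCount <- geo$crossingCount
    s <- shgStack(rc$stack, voxelUm = voxelUm, meta = meta,
                  processingLog = list(list(op = "synthesize",
                                            seed = truth@seed,
                                            clipped = rc$clipped)))
    list(stack = s, fibers = geo$fibers, truth = truth)
  })
}

#' Generate a dorsal/ventral phantom pair differing only in intensity
#'
#' Both stacks share one fiber geometry and identical noise statistics; the
#' ventral stack's mean on-fiber intensity is the dorsal one multiplied by
#' \code{intensityRatio}, exactly, before noise. If the scaled intensity
#' can exceed the 12-bit ceiling a clipping warning is raised and flagged in
#' the returned stack's processing log.
#'
#' @param truth a \code{PhantomTruth}; \code{intensityScale} sets the dorsal
#'   (reference) on-fiber intensity.
#' @param intensityRatio ventral-to-dorsal on-fiber intensity ratio (> 0).
#' @param shapePx,voxelUm,psfSigmaUm,retryBudget as in
#'   \code{\link{genFiberStack}}.
#' @return \code{list(ventral, dorsal, fibers, truth, trueRatio)}.
#' @export
genPairedStacks <- function(truth, intensityRatio = 2,
                            shapePx = c(y = 320L, x = 320L, z = 8L),
                            voxelUm = c(y = 1.21, x = 1.21, z = 10.62),
                            psfSigmaUm = c(y = 0.13, x = 0.13, z = 0.58),
                            retryBudget = 200L) {
  stopifnot(intensityRatio > 0)
  shapePx <- as.integer(shapePx)
  extent <- (shapePx - 1L) * voxelUm
  withSeed(truth@seed, {
    geo <- .genFiberGeometry(truth, extent, sliceZUm = (seq_len(shapePx[3]) - 1) *
                               voxelUm[3], retryBudget = retryBudget)
    mask <- renderFiberSet(geo$fibers, shapePx, voxelUm)
    dor <- .renderAndCorrupt(mask, truth@intensityScale, voxelUm, psfSigmaUm,
                             truth@noiseSigma, truth@poissonNoise)
    ven <- .renderAndCorrupt(mask, truth@intensityScale * intensityRatio,
                             voxelUm, psfSigmaUm, truth@noiseSigma,
                             truth@poissonNoise)
    if (ven$clipped || dor$clipped)
      warning("on-fiber intensity exceeds the 12-bit ceiling; values clipped at 4095")
    truth@fiberAnglesDeg <- geo$anglesDeg
    mkStack <- function(rc, surface) {
      shgStack(rc$stack, voxelUm = voxelUm,
               meta = sampleMeta(surface = surface,
                                 distanceFromTipCm = 0,
                                 specimenId = "phantom-pair"),
               processingLog = list(list(op = "synthesize",
                                         seed = truth@seed,
                                         clipped = rc$clipped)))
    }
    list(ventral = mkStack(ven, "ventral"), dorsal = mkStack(dor, "dorsal"),
         fibers = geo$fibers, truth = truth, trueRatio = intensityRatio)
  })
}
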