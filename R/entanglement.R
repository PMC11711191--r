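# Fiber crossing ("entanglement") analysis: a crossing is an event where two
# distinct fibers approach within a contact distance (default: the sum of
# their radii) with in-plane tangent angles at least a transversality
# threshold apart; contiguous contact events between one fiber pair are
# merged (declustered) into a single crossing.

.emptyCrossingResult <- function(volume = NA_real_) {
  new("CrossingResult", crossingCount = 0L,
      crossingLocations = matrix(numeric(0), 0, 3,
                                 dimnames = list(NULL, c("y", "x", "z"))),
      pairIds = matrix(integer(0), 0, 2,
                       dimnames = list(NULL, c("fiber_a", "fiber_b"))),
      roiVolumeUm3 = volume,
      densityPerUm3 = if (is.na(volume)) NA_real_ else 0)
}

#' Detect crossings between distinct fibers
#'
#' For every fiber pair, finds closest-approach events between the two
#' polylines within the contact distance whose local in-plane tangents
#' differ by at least \code{minCrossAngleDeg} (near-parallel contact is
#' bundling, not crossing). Events from one pair within the declustering
#' radius (\code{declusterFactor} times the contact distance) of an accepted
#' crossing are merged into it. Self-crossings are never counted. The count
#' is invariant to fiber enumeration order.
#'
#' @param f a \code{FiberSet}.
#' @param contactDistUm contact distance in um; defaults per pair to the sum
#'   of the two fibers' radii (an error if radii are missing).
#' @param minCrossAngleDeg minimum in-plane crossing angle (default 15).
#' @param declusterFactor declustering radius as a multiple of the contact
#'   distance (default 2).
#' @param mergeRadiusUm optional spatial merge radius: crossings from
#'   different fiber pairs within this distance collapse into one. Off (0)
#'   by default, where the count is the exact per-pair geometric rule; turn
#'   on when the input fibers are traced fragments, where one physical
#'   crossing can surface through several fragment pairs.
#' @return A \code{CrossingResult} with \code{NA} volume/density (no ROI).
#' @export
detectCrossings <- function(f, contactDistUm = NULL, minCrossAngleDeg = 15,
                            declusterFactor = 2, mergeRadiusUm = 0) {
  n <- length(f@fibers)
  if (is.null(contactDistUm) && any(is.na(f@radiusUm)))
    stop("fiber radii missing and no explicit contactDistUm given")
  if (n < 2) return(.emptyCrossingResult())
  boxes <- t(vapply(f@fibers, function(p)
    c(min(p[, 1]), max(p[, 1]), min(p[, 2]), max(p[, 2]),
      min(p[, 3]), max(p[, 3])), numeric(6)))
  locs <- NULL; pairs <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dmax <- if (is.null(contactDistUm)) f@radiusUm[i] + f@radiusUm[j]
              else contactDistUm
      if (boxes[i, 1] > boxes[j, 2] + dmax ||
          boxes[j, 1] > boxes[i, 2] + dmax ||
          boxes[i, 3] > boxes[j, 4] + dmax ||
          boxes[j, 3] > boxes[i, 4] + dmax ||
          boxes[i, 5] > boxes[j, 6] + dmax ||
          boxes[j, 5] > boxes[i, 6] + dmax) next
      ev <- cpp_polyline_contacts(f@fibers[[i]], f@fibers[[j]], dmax)
      if (!nrow(ev)) next
      keep <- angleDiff180(ev[, "ang_a"], ev[, "ang_b"]) >= minCrossAngleDeg
      ev <- ev[keep, , drop = FALSE]
      if (!nrow(ev)) next
      ev <- ev[order(ev[, "dist"]), , drop = FALSE]
      accepted <- NULL
      declust <- declusterFactor * dmax
      for (r in seq_len(nrow(ev))) {
        p <- ev[r, c("y", "x", "z")]
        if (!is.null(accepted)) {
          d <- sqrt(rowSums((accepted - matrix(p, nrow(accepted), 3,
                                               byrow = TRUE))^2))
          if (any(d <= declust)) next
        }
        accepted <- rbind(accepted, p)
      }
      locs <- rbind(locs, accepted)
      pairs <- rbind(pairs, matrix(c(i, j), nrow(accepted), 2, byrow = TRUE))
    }
  }
  if (is.null(locs)) return(.emptyCrossingResult())
  if (mergeRadiusUm > 0 && nrow(locs) > 1) {
    # order-independent greedy collapse: scan in lexicographic location
    # order, keeping a crossing only if no kept crossing lies within reach
    ord <- order(locs[, 1], locs[, 2], locs[, 3])
    locs <- locs[ord, , drop = FALSE]
    pairs <- pairs[ord, , drop = FALSE]
    keep <- rep(TRUE, nrow(locs))
    for (a in 2:nrow(locs)) {
      prior <- which(keep[seq_len(a - 1L)])
      if (!length(prior)) next
      d <- sqrt(rowSums((locs[prior, , drop = FALSE] -
                         matrix(locs[a, ], length(prior), 3,
                                byrow = TRUE))^2))
      if (any(d <= mergeRadiusUm)) keep[a] <- FALSE
    }
    locs <- locs[keep, , drop = FALSE]
    pairs <- pairs[keep, , drop = FALSE]
  }
  dimnames(locs) <- list(NULL, c("y", "x", "z"))
  dimnames(pairs) <- list(NULL, c("fiber_a", "fiber_b"))
  new("CrossingResult", crossingCount = nrow(locs),
      crossingLocations = locs, pairIds = pairs,
      roiVolumeUm3 = NA_real_, densityPerUm3 = NA_real_)
}

#' Crossing density within a 3D ROI
#'
#' Restricts detected crossings to a half-open box (a square of
#' \code{roiPx} pixels extruded over \code{depthUm} of depth) and reports
#' crossings per cubic micrometre. Half-open bounds make counts over
#' disjoint adjacent ROIs exactly additive.
#'
#' @param f a \code{FiberSet}.
#' @param roiPx in-plane ROI size in pixels (default 200 x 200).
#' @param depthUm extruded depth in um (default 100).
#' @param voxelUm voxel sizes (y, x, z) um (in-plane sizes convert
#'   \code{roiPx} to physical units).
#' @param originUm box origin (y, x, z) in um (default the volume corner).
#' @param contactDistUm,minCrossAngleDeg,declusterFactor passed to
#'   \code{\link{detectCrossings}}.
#' @return A \code{CrossingResult} with volume and density filled in.
#' @export
crossingDensity <- function(f, roiPx = c(200, 200), depthUm = 100,
                            voxelUm = c(y = 1.21, x = 1.21, z = 10.62),
                            originUm = c(0, 0, 0), contactDistUm = NULL,
                            minCrossAngleDeg = 15, declusterFactor = 2,
                            mergeRadiusUm = 0) {
  sideY <- roiPx[1] * voxelUm[[1]]
  sideX <- roiPx[2] * voxelUm[[2]]
  volume <- sideY * sideX * depthUm
  if (volume <= 0) stop("degenerate ROI: zero volume")
  det <- detectCrossings(f, contactDistUm, minCrossAngleDeg, declusterFactor,
                         mergeRadiusUm)
  if (det@crossingCount == 0) return(.emptyCrossingResult(volume))
  L <- det@crossingLocations
  inBox <- L[, "y"] >= originUm[1] & L[, "y"] < originUm[1] + sideY &
           L[, "x"] >= originUm[2] & L[, "x"] < originUm[2] + sideX &
           L[, "z"] >= originUm[3] & L[, "z"] < originUm[3] + depthUm
  locs <- L[inBox, , drop = FALSE]
  new("CrossingResult", crossingCount = nrow(locs),
      crossingLocations = locs,
      pairIds = det@pairIds[inBox, , drop = FALSE],
      roiVolumeUm3 = volume, densityPerUm3 = nrow(locs) / volume)
}

#' Crossing density over several random ROIs
#'
#' Convenience wrapper placing \code{nRois} ROI boxes at seeded random
#' in-plane origins within the fiber field and reporting the per-ROI
#' densities with their mean and sd.
#'
#' @param f a \code{FiberSet}.
#' @param nRois number of ROIs (default 4).
#' @param extentUm in-plane field extent (y, x) in um; inferred from the
#'   fiber coordinates when missing.
#' @param seed integer seed for ROI placement.
#' @inheritParams crossingDensity
#' @return list with \code{perRoi}, \code{densityMean}, \code{densitySd}.
#' @export
crossingDensityRois <- function(f, nRois = 4L, roiPx = c(200, 200),
                                depthUm = 100,
                                voxelUm = c(y = 1.21, x = 1.21, z = 10.62),
                                extentUm = NULL, seed = NULL,
                                contactDistUm = NULL, minCrossAngleDeg = 15,
                                declusterFactor = 2, mergeRadiusUm = 0) {
  if (is.null(extentUm)) {
    allp <- do.call(rbind, f@fibers)
    extentUm <- c(max(allp[, 1]), max(allp[, 2]))
  }
  sideY <- roiPx[1] * voxelUm[[1]]
  sideX <- roiPx[2] * voxelUm[[2]]
  withSeed(seed, {
    res <- lapply(seq_len(nRois), function(k) {
      oy <- stats::runif(1, 0, max(0, extentUm[1] - sideY))
      ox <- stats::runif(1, 0, max(0, extentUm[2] - sideX))
      crossingDensity(f, roiPx, depthUm, voxelUm, originUm = c(oy, ox, 0),
                      contactDistUm = contactDistUm,
                      minCrossAngleDeg = minCrossAngleDeg,
                      declusterFactor = declusterFactor,
                      mergeRadiusUm = mergeRadiusUm)
    })
    dens <- vapply(res, function(r) r@densityPerUm3, 1.0)
    list(perRoi = res, densityMean = mean(dens),
         densitySd = if (nRois > 1) stats::sd(dens) else 0)
  })
}
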