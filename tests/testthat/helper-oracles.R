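# Independent oracles and small fixture builders shared across tests.
# These deliberately use different algorithms/code paths than the package.

# Brute-force grayscale opening by a spherical-cap element: per-pixel window
# slicing (vectorized over the structuring element, looped over pixels).
oracleRollingBallBackground <- function(m, r) {
  off <- seq(-floor(r), floor(r))
  d2 <- outer(off^2, off^2, "+")
  hgt <- sqrt(pmax(r^2 - d2, 0)) - r
  inside <- d2 <= r^2
  nr <- nrow(m); nc <- ncol(m)
  morph <- function(img, erode) {
    out <- matrix(NA_real_, nr, nc)
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        ii <- i + off; jj <- j + off
        okr <- ii >= 1 & ii <= nr; okc <- jj >= 1 & jj <= nc
        win <- img[ii[okr], jj[okc], drop = FALSE]
        h <- hgt[okr, okc, drop = FALSE]
        ins <- inside[okr, okc, drop = FALSE]
        out[i, j] <- if (erode) min((win - h)[ins]) else max((win + h)[ins])
      }
    }
    out
  }
  # symmetric element: dilation with the same offsets
  morph(morph(m, TRUE), FALSE)
}

# Exact minimum distance between two 3D segments by convex optimization
# (the squared distance is convex in the two arclength parameters).
oracleSegmentDistance <- function(A, B) {
  f <- function(st) {
    p <- A[1, ] + st[1] * (A[2, ] - A[1, ])
    q <- B[1, ] + st[2] * (B[2, ] - B[1, ])
    sum((p - q)^2)
  }
  o <- stats::optim(c(0.5, 0.5), f, method = "L-BFGS-B", lower = 0, upper = 1)
  sqrt(o$value)
}

# Exhaustive pairwise crossing count on straight-segment truth fibers.
oracleCrossingCount <- function(f, contactDistUm = NULL,
                                minCrossAngleDeg = 15) {
  n <- nFibers(f)
  if (n < 2) return(0L)
  cnt <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      A <- fibers(f)[[i]]; B <- fibers(f)[[j]]
      dmax <- if (is.null(contactDistUm)) {
        f@radiusUm[i] + f@radiusUm[j]
      } else contactDistUm
      angA <- (atan2(A[2, 2] - A[1, 2], A[2, 1] - A[1, 1]) * 180 / pi) %% 180
      angB <- (atan2(B[2, 2] - B[1, 2], B[2, 1] - B[1, 1]) * 180 / pi) %% 180
      d <- abs(angA - angB); d <- min(d, 180 - d)
      if (d >= minCrossAngleDeg && oracleSegmentDistance(A, B) <= dmax)
        cnt <- cnt + 1L
    }
  }
  cnt
}

# A FiberSet of evenly spaced, non-overlapping straight tubes at one angle,
# distributed over z slice planes (deterministic, no RNG).
parallelTubeSet <- function(n, angleDeg, extentUm = c(380, 380),
                            nSlices = 5L, zStepUm = 10.62, radiusUm = 5) {
  perSlice <- ceiling(n / nSlices)
  segs <- list(); k <- 0L
  th <- angleDeg * pi / 180
  d <- c(cos(th), sin(th), 0)
  # offsets transverse to the fiber direction
  tv <- c(-d[2], d[1], 0)
  span <- 0.8 * min(extentUm)
  for (s in seq_len(nSlices)) {
    for (i in seq_len(perSlice)) {
      if (k >= n) break
      k <- k + 1L
      offset <- (i - (perSlice + 1) / 2) * (span / perSlice)
      ctr <- c(extentUm[1] / 2, extentUm[2] / 2, (s - 1) * zStepUm) +
        offset * tv
      segs[[k]] <- rbind(ctr - 0.45 * min(extentUm) * d,
                         ctr + 0.45 * min(extentUm) * d)
    }
  }
  fiberSet(segs, radiusUm = radiusUm)
}
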