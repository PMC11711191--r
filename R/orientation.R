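# Collagen fiber extraction and orientation classification.
#
# Fibers are extracted per slice with a multiscale Hessian ridge filter
# (scales bracketing the expected fiber radius), a salience threshold that
# keeps the top fraction of pixels by ridge response, Zhang-Suen
# skeletonization and junction-aware tracing; traced centerlines are
# refined to subpixel precision against the ridge response, fragments of one
# fiber are re-chained within and across slices, and the per-fiber angle is
# the total-least-squares line through the polyline, measured from the
# outward normal in [0, 180).

# Scale-normalized bright-ridge response of a 2D image: the negated smaller
# Hessian eigenvalue, floored at 0, maximized over scales.
ridgeResponse <- function(m, scalesPx) {
  out <- matrix(0, nrow(m), ncol(m))
  for (s in scalesPx) {
    g0 <- gaussDerivKernel(s, 0)
    g1 <- gaussDerivKernel(s, 1)
    g2 <- gaussDerivKernel(s, 2)
    gyy <- cpp_sep_conv(m, g2, g0)
    gxx <- cpp_sep_conv(m, g0, g2)
    gxy <- cpp_sep_conv(m, g1, g1)
    disc <- sqrt((gxx - gyy)^2 + 4 * gxy^2)
    lam <- (gxx + gyy - disc) / 2          # smaller eigenvalue
    resp <- pmax(0, -lam) * s^2            # scale-normalized
    out <- pmax(out, resp)
  }
  out
}

# Salience threshold: keep the top `keepFraction` of image pixels ranked by
# ridge response, restricted to pixels with positive response (the analogue
# of keeping that fraction of transform coefficients). keepFraction = 1
# retains exactly the positive-response support.
thresholdTopPixels <- function(resp, keepFraction) {
  stopifnot(keepFraction > 0, keepFraction <= 1)
  pos <- resp > 0
  if (!any(pos) || keepFraction >= 1) return(pos)
  nKeep <- min(sum(pos), ceiling(keepFraction * length(resp)))
  cut <- sort(resp[pos], decreasing = TRUE)[nKeep]
  resp >= cut & pos
}

# 8-neighbour count of each skeleton pixel.
neighborCount <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- skel
  acc <- matrix(0L, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    acc <- acc + pad[(2 + dy):(nr + 1 + dy), (2 + dx):(nc + 1 + dx)]
  }
  acc
}

# Order the pixels of one skeletal branch (no junctions) into a path by
# walking from an endpoint. `pix` is an n x 2 matrix of (row, col); lookup
# goes through a dense index map so the walk is linear in branch length.
orderBranch <- function(pix) {
  n <- nrow(pix)
  if (n <= 2) return(pix)
  r0 <- min(pix[, 1]) - 1L; c0 <- min(pix[, 2]) - 1L
  idxMat <- matrix(0L, max(pix[, 1]) - r0 + 2L, max(pix[, 2]) - c0 + 2L)
  idxMat[cbind(pix[, 1] - r0, pix[, 2] - c0)] <- seq_len(n)
  off <- rbind(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L), c(0L, 1L),
               c(1L, -1L), c(1L, 0L), c(1L, 1L))
  nbrs <- function(i) {
    rr <- pix[i, 1] - r0 + off[, 1]
    cc <- pix[i, 2] - c0 + off[, 2]
    ok <- rr >= 1L & rr <= nrow(idxMat) & cc >= 1L & cc <= ncol(idxMat)
    v <- idxMat[cbind(rr[ok], cc[ok])]
    v[v > 0L]
  }
  deg <- vapply(seq_len(n), function(i) length(nbrs(i)), 1L)
  start <- which(deg <= 1L)[1]
  if (is.na(start)) start <- 1L
  visited <- logical(n)
  path <- integer(n)
  cur <- start
  len <- 0L
  repeat {
    visited[cur] <- TRUE
    len <- len + 1L
    path[len] <- cur
    nb <- nbrs(cur)
    nxt <- nb[!visited[nb]]
    if (!length(nxt)) break
    cur <- nxt[1]
  }
  pix[path[seq_len(len)], , drop = FALSE]
}

# Bilinear sample of a matrix at fractional (row, col) positions.
.bilinear <- function(img, y, x) {
  y <- pmin(pmax(y, 1), nrow(img) - 1e-6)
  x <- pmin(pmax(x, 1), ncol(img) - 1e-6)
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0; fx <- x - x0
  img[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
    img[cbind(y0 + 1, x0)] * fy * (1 - fx) +
    img[cbind(y0, x0 + 1)] * (1 - fy) * fx +
    img[cbind(y0 + 1, x0 + 1)] * fy * fx
}

# Subpixel centerline refinement: move each path point transverse to the
# local direction onto the response-weighted centroid of the ridge profile,
# then smooth away the residual staircase wiggle. `px` is an n x 2 matrix
# of (row, col) in pixel units. Thin wrapper over the compiled kernel.
refineCenterline <- function(px, resp, iters = 2L, halfWidth = 3) {
  cpp_refine_centerline(px, resp, as.integer(iters), halfWidth)
}

# Tube radius of a traced branch from the image itself: the transverse
# intensity profile's half width at half maximum, median over sampled path
# points. Unlike a distance transform of the thresholded support, this does
# not shrink when the salience threshold keeps only fiber cores.
.traceRadiusUm <- function(m, pix, pixelUm) {
  n <- nrow(pix)
  idx <- unique(round(seq(1, n, length.out = min(15L, n))))
  k <- pmin(pmax(idx, 3L), max(1L, n - 2L))
  lo <- pmax(k - 2L, 1L); hi <- pmin(k + 2L, n)
  d <- pix[hi, , drop = FALSE] - pix[lo, , drop = FALSE]
  len <- sqrt(rowSums(d^2)); len[len == 0] <- 1
  d <- d / len
  tv <- cbind(-d[, 2], d[, 1])
  offs <- seq(0, 8, by = 0.5)
  prof <- vapply(offs, function(o) {
    right <- .bilinear(m, pix[idx, 1] + o * tv[, 1],
                       pix[idx, 2] + o * tv[, 2])
    left <- .bilinear(m, pix[idx, 1] - o * tv[, 1],
                      pix[idx, 2] - o * tv[, 2])
    (right + left) / 2
  }, numeric(length(idx)))
  if (is.null(dim(prof))) prof <- matrix(prof, nrow = 1)
  peak <- prof[, 1]
  hw <- vapply(seq_along(idx), function(r) {
    if (peak[r] <= 0) return(0)
    below <- which(prof[r, ] < peak[r] / 2)
    if (!length(below)) return(max(offs))
    offs[below[1]]
  }, 1.0)
  stats::median(hw) * mean(pixelUm)
}

# Direction (unit vector (dy, dx) in um) at a polyline end, pointing outward
# from the interior toward that endpoint; averaged over up to `k` steps.
.endDirectionUm <- function(p, end, k = 10L) {
  n <- nrow(p)
  k <- min(k, n - 1L)
  if (end == 1L) d <- p[1, 1:2] - p[1 + k, 1:2]
  else d <- p[n, 1:2] - p[n - k, 1:2]
  nrm <- sqrt(sum(d^2))
  if (nrm == 0) c(1, 0) else d / nrm
}

# Merge fiber fragments that belong to one physical fiber. Where fibers
# cross, the ridge response dips and traces break; where a tilted fiber
# leaves a z slice, its trace continues in the neighbouring slice. Chain
# polyline ends that lie within `gapUm` of each other in-plane, within
# `dzMaxUm` in z, whose directions continue nearly straight (turn below
# `maxTurnDeg`) and whose connecting step also aligns with the direction.
# Greedy from the straightest candidate; each end links at most once.
# A second, long-range tier (up to `gapFarUm`) bridges the wide holes that
# crossings punch into the traced support, but only under strict
# collinearity (`farTurnDeg`), so it cannot bend a chain.
# `polys` is a list of n x 3 um matrices; `aux` a list of equal-length
# per-polyline vectors (salience, radius) combined by length weighting.
mergeFiberChains <- function(polys, aux, gapUm, maxTurnDeg = 30,
                             dzMaxUm = 0, gapFarUm = gapUm,
                             farTurnDeg = 12, farMinLenUm = 0,
                             lateralTolUm = 5, bridgeOk = NULL) {
  nb <- length(polys)
  if (nb < 2) return(list(polys = polys, aux = aux))
  ends <- do.call(rbind, lapply(seq_len(nb), function(i) {
    p <- polys[[i]]
    rbind(c(i, 1L, p[1, ]), c(i, 2L, p[nrow(p), ]))
  }))
  ne <- nrow(ends)
  plen <- vapply(polys, polylineLength, 1.0)
  dirs <- lapply(seq_len(ne), function(e)
    .endDirectionUm(polys[[ends[e, 1]]], ends[e, 2]))
  # vectorized prefilter on in-plane gap and z proximity
  dy <- outer(ends[, 3], ends[, 3], "-")
  dx <- outer(ends[, 4], ends[, 4], "-")
  dzm <- abs(outer(ends[, 5], ends[, 5], "-"))
  close <- dy^2 + dx^2 <= max(gapUm, gapFarUm)^2 & dzm <= dzMaxUm + 1e-9 &
    upper.tri(dzm) & outer(ends[, 1], ends[, 1], "!=")
  pairsIdx <- which(close, arr.ind = TRUE)
  cand <- NULL
  for (r0 in seq_len(nrow(pairsIdx))) {
    ea <- pairsIdx[r0, 1]; eb <- pairsIdx[r0, 2]
    gap <- ends[eb, 3:4] - ends[ea, 3:4]
    glen <- sqrt(sum(gap^2))
    far <- glen > gapUm
    if (far && (plen[ends[ea, 1]] < farMinLenUm ||
                plen[ends[eb, 1]] < farMinLenUm)) next
    turnTol <- if (far) farTurnDeg else maxTurnDeg
    da <- dirs[[ea]]; db <- dirs[[eb]]
    turn <- acos(pmin(1, pmax(-1, sum(da * -db)))) * 180 / pi
    if (turn > turnTol) next
    if (glen > 2) {
      # continuation must stay on line: lateral offset of the step from
      # each fragment's direction kills merges of distinct parallel fibers.
      # The tolerance shrinks for short fragments, bounding the angle a
      # merge can impose on the combined trace.
      latTol <- max(3, min(lateralTolUm,
                    0.04 * (plen[ends[ea, 1]] + plen[ends[eb, 1]])))
      latA <- abs(gap[1] * da[2] - gap[2] * da[1])
      latB <- abs(gap[1] * db[2] - gap[2] * db[1])
      if (latA > latTol || latB > latTol) next
    }
    # a long bridge must run over actual signal (the crossing region it
    # spans is part of a fiber), not across empty background
    if (!is.null(bridgeOk) && glen > 6 &&
        !bridgeOk(ends[ea, 3:5], ends[eb, 3:5])) next
    cand <- rbind(cand, c(ea, eb, turn))
  }
  if (is.null(cand)) return(list(polys = polys, aux = aux))
  linkOf <- array(0L, dim = c(nb, 2, 2))
  usedEnd <- rep(FALSE, ne)
  for (r in order(cand[, 3])) {
    ea <- cand[r, 1]; eb <- cand[r, 2]
    if (usedEnd[ea] || usedEnd[eb]) next
    usedEnd[ea] <- usedEnd[eb] <- TRUE
    ba <- ends[ea, 1]; enda <- ends[ea, 2]
    bb <- ends[eb, 1]; endb <- ends[eb, 2]
    linkOf[ba, enda, ] <- c(bb, endb)
    linkOf[bb, endb, ] <- c(ba, enda)
  }
  orient <- function(p, firstEnd) if (firstEnd == 1L) p
            else p[rev(seq_len(nrow(p))), , drop = FALSE]
  visited <- rep(FALSE, nb)
  outP <- list(); outA <- list()
  for (i in seq_len(nb)) {
    if (visited[i]) next
    startEnd <- if (linkOf[i, 1, 1] == 0L) 1L
                else if (linkOf[i, 2, 1] == 0L) 2L else 1L
    chainP <- orient(polys[[i]], startEnd)
    members <- i
    visited[i] <- TRUE
    curBranch <- i; curEnd <- 3L - startEnd
    repeat {
      nxt <- linkOf[curBranch, curEnd, ]
      if (nxt[1] == 0L || visited[nxt[1]]) break
      chainP <- rbind(chainP, orient(polys[[nxt[1]]], nxt[2]))
      visited[nxt[1]] <- TRUE
      members <- c(members, nxt[1])
      curBranch <- nxt[1]; curEnd <- 3L - nxt[2]
    }
    wts <- vapply(members, function(m) nrow(polys[[m]]), 1L)
    comb <- lapply(seq_along(aux), function(a)
      sum(vapply(members, function(m) aux[[a]][m], 1.0) * wts) / sum(wts))
    outP[[length(outP) + 1]] <- chainP
    outA[[length(outA) + 1]] <- unlist(comb)
  }
  aux2 <- lapply(seq_along(aux), function(a)
    vapply(outA, function(v) v[a], 1.0))
  list(polys = outP, aux = aux2)
}

.mergeToFixpoint <- function(polys, aux, gapUm, maxTurnDeg, dzMaxUm,
                             gapFarUm = gapUm, farTurnDeg = 15,
                             bridgeOk = NULL) {
  repeat {
    n0 <- length(polys)
    res <- mergeFiberChains(polys, aux, gapUm, maxTurnDeg, dzMaxUm,
                            gapFarUm, farTurnDeg, bridgeOk = bridgeOk)
    polys <- res$polys; aux <- res$aux
    if (length(polys) == n0) break
  }
  list(polys = polys, aux = aux)
}

# Bridge validator over one slice: the straight connector between two trace
# ends must run over fiber-level signal. `m` in pixel units, ends in um.
.sliceBridgeValidator <- function(m, pixelUm, onFiberLevel, frac = 0.4) {
  function(pa, pb) {
    t <- seq(0, 1, length.out = 11)
    y <- (pa[1] + t * (pb[1] - pa[1])) / pixelUm[1] + 1
    x <- (pa[2] + t * (pb[2] - pa[2])) / pixelUm[2] + 1
    mean(.bilinear(m, y, x)) >= frac * onFiberLevel
  }
}

# Core 2D fragment extraction on one slice: traced, subpixel-refined, merged
# within the slice, but not yet length-filtered (fragments may continue in
# neighbouring slices). pixelUm = (y, x) um/px; zUm the physical slice z.
.extractFragments2d <- function(m, pixelUm, zUm, keepFraction, radiusUm,
                                maxTurnDeg = 30) {
  radiusPx <- radiusUm / mean(pixelUm)
  scales <- pmax(0.8, radiusPx * c(0.5, 0.75, 1.0))
  resp <- ridgeResponse(m, scales)
  mask <- thresholdTopPixels(resp, keepFraction)
  emptyResult <- list(polys = list(), aux = list(numeric(0), numeric(0)))
  if (!any(mask)) return(emptyResult)
  # bridge hairline gaps (e.g. response dips where fibers cross)
  mask <- EBImage::closing(matrix(as.numeric(mask), nrow(mask)),
                           EBImage::makeBrush(3, "box")) > 0
  skel <- cpp_thin(matrix(as.integer(mask), nrow(mask)))
  if (!any(skel == 1L)) return(emptyResult)
  nbc <- neighborCount(skel)
  junction <- skel == 1L & nbc >= 3L
  seg <- matrix(as.integer(skel == 1L & !junction), nrow(skel))
  branches <- cpp_trace_branches(seg)
  if (!length(branches)) return(emptyResult)
  polys <- list(); sal <- numeric(0); rad <- numeric(0)
  for (pix in branches) {
    if (nrow(pix) < 2) next
    salK <- mean(resp[pix])
    radK <- .traceRadiusUm(m, pix, pixelUm)
    ref <- refineCenterline(pix, resp)
    polys[[length(polys) + 1]] <-
      cbind((ref[, 1] - 1) * pixelUm[1], (ref[, 2] - 1) * pixelUm[2], zUm)
    sal <- c(sal, salK)
    rad <- c(rad, radK)
  }
  if (!length(polys)) return(emptyResult)
  onFiber <- stats::median(m[mask])
  .mergeToFixpoint(polys, list(sal, rad),
                   gapUm = max(6, 4 * radiusUm), maxTurnDeg = maxTurnDeg,
                   dzMaxUm = 0, gapFarUm = 10 * radiusUm,
                   bridgeOk = .sliceBridgeValidator(m, pixelUm, onFiber))
}

# RMS transverse deviation of a polyline from its total-least-squares line.
tlsResidual <- function(p) {
  yx <- sweep(p[, 1:2, drop = FALSE], 2, colMeans(p[, 1:2, drop = FALSE]))
  e <- eigen(crossprod(yx) / max(1, nrow(yx) - 1), symmetric = TRUE)
  sqrt(max(0, e$values[2]))
}

# Interior of a polyline: a few points at each end border junction gaps and
# carry response from both crossing fibers, so the line fit and the quality
# gate use the trimmed interior while the stored polyline stays complete.
.polyInterior <- function(p, trim = 3L) {
  n <- nrow(p)
  k <- min(trim, (n - 6L) %/% 2L)
  if (k > 0L) p[(1L + k):(n - k), , drop = FALSE] else p
}

# Straightness gate with kink splitting: a trace only carries a meaningful
# single orientation if its RMS transverse residual is small relative to
# its length. Crooked traces (braid artifacts between overlapping fibers,
# occasional bad chain merges) are split at the point of largest transverse
# deviation and the parts re-examined, so the underlying straight pieces
# survive with their own angles; irreducibly crooked stubs are dropped.
.straightPieces <- function(p, maxResidFrac, residFloorUm, depth = 0L,
                            residCapUm = 1.2) {
  q <- .polyInterior(p)
  resid <- tlsResidual(q)
  # the tolerance is relative to length but capped: a very long chain may
  # not buy itself a large absolute deviation (that is how wrongly grouped
  # near-parallel fibers would slip through)
  if (resid <= max(residFloorUm, min(maxResidFrac * polylineLength(p),
                                     residCapUm)))
    return(list(p))
  if (nrow(p) < 12L || depth >= 6L) return(list())
  # split at the largest deviation from the TLS line (interior coords)
  yx <- sweep(q[, 1:2, drop = FALSE], 2, colMeans(q[, 1:2, drop = FALSE]))
  e <- eigen(crossprod(yx) / max(1, nrow(yx) - 1), symmetric = TRUE)
  dev <- abs(yx %*% e$vectors[, 2])
  kq <- which.max(dev)
  k <- min(max(kq + (nrow(p) - nrow(q)) %/% 2L, 4L), nrow(p) - 4L)
  c(.straightPieces(p[1:k, , drop = FALSE], maxResidFrac, residFloorUm,
                    depth + 1L),
    .straightPieces(p[(k + 1L):nrow(p), , drop = FALSE], maxResidFrac,
                    residFloorUm, depth + 1L))
}

# Group traces that are pieces of one physical fiber: the window statistics
# are per fiber, so fragments left by crossings (and duplicate strands from
# wide support) must be counted once. Two traces belong to one fiber when
# their orientations agree, each lies on the other's total-least-squares
# line (small lateral offset), and they sit at comparable depth. Groups are
# closed transitively; each group's fragments are concatenated in order of
# their projection along the common direction, so the grouped polyline runs
# along the true fiber (including over the crossings that cut it).
.groupCollinear <- function(polys, aux, angTolDeg = 8, latTolUm = 4.5,
                            dzTolUm = 40) {
  n <- length(polys)
  if (n < 2) return(list(polys = polys, aux = aux))
  ang <- vapply(lapply(polys, .polyInterior), polylineAngle, 1.0)
  ctr <- t(vapply(polys, function(p) colMeans(p), numeric(3)))
  dir <- cbind(cos(ang * pi / 180), sin(ang * pi / 180))
  parent <- seq_len(n)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (angleDiff180(ang[i], ang[j]) > angTolDeg) next
      if (abs(ctr[i, 3] - ctr[j, 3]) > dzTolUm) next
      dv <- ctr[j, 1:2] - ctr[i, 1:2]
      latI <- abs(dv[1] * dir[i, 2] - dv[2] * dir[i, 1])
      latJ <- abs(dv[1] * dir[j, 2] - dv[2] * dir[j, 1])
      if (latI > latTolUm || latJ > latTolUm) next
      # fragments of one fiber are sequential along it; two traces of
      # comparable length that overlap longitudinally are side-by-side
      # distinct fibers (a much shorter overlapping sliver is a tracing
      # artifact of the longer fiber and is absorbed)
      u <- dir[i, ]
      pi1 <- polys[[i]][, 1] * u[1] + polys[[i]][, 2] * u[2]
      pj1 <- polys[[j]][, 1] * u[1] + polys[[j]][, 2] * u[2]
      spanI <- max(pi1) - min(pi1); spanJ <- max(pj1) - min(pj1)
      ov <- min(max(pi1), max(pj1)) - max(min(pi1), min(pj1))
      if (ov > 0.3 * min(spanI, spanJ) &&
          min(spanI, spanJ) > 0.33 * max(spanI, spanJ)) next
      ri <- findRoot(i); rj <- findRoot(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), findRoot, 1L)
  outP <- list(); outA <- vector("list", length(aux))
  for (a in seq_along(aux)) outA[[a]] <- numeric(0)
  for (r in unique(roots)) {
    members <- which(roots == r)
    if (length(members) == 1L) {
      outP[[length(outP) + 1]] <- polys[[members]]
      for (a in seq_along(aux))
        outA[[a]] <- c(outA[[a]], aux[[a]][members])
      next
    }
    pts <- do.call(rbind, polys[members])
    # undirected orientations: align members to the first before averaging
    # (0 and 179 degrees are 1 degree apart but have opposite unit vectors)
    dd <- dir[members, , drop = FALSE]
    flip <- as.vector(dd %*% dir[members[1], ]) < 0
    dd[flip, ] <- -dd[flip, , drop = FALSE]
    u <- colMeans(dd)
    u <- u / sqrt(sum(u^2))
    proj <- pts[, 1] * u[1] + pts[, 2] * u[2]
    merged <- pts[order(proj), , drop = FALSE]
    # a genuine fiber's fragments assemble into a straight chain; if the
    # merged chain is not straight the grouping was wrong — keep the
    # members separate rather than emit a crooked composite
    mlen <- polylineLength(merged)
    if (tlsResidual(merged) > max(0.25, min(0.01 * mlen, 1.2))) {
      for (m in members) {
        outP[[length(outP) + 1]] <- polys[[m]]
        for (a in seq_along(aux))
          outA[[a]] <- c(outA[[a]], aux[[a]][m])
      }
      next
    }
    outP[[length(outP) + 1]] <- merged
    wts <- vapply(members, function(m) nrow(polys[[m]]), 1L)
    for (a in seq_along(aux))
      outA[[a]] <- c(outA[[a]],
                     sum(aux[[a]][members] * wts) / sum(wts))
  }
  list(polys = outP, aux = outA)
}

.fiberSetFrom <- function(polys, aux, minLengthUm, radiusUm = 5,
                          maxResidFrac = 0.01, residFloorUm = 0.25,
                          minRadiusFrac = 0.35, maxRadiusFrac = 1.3,
                          minSalienceFrac = 0.05) {
  # traces must carry real ridge signal: where the salience budget exceeds
  # the fiber content, the surplus retained pixels are noise ridges whose
  # traces have orders-of-magnitude weaker response than fiber traces
  salRef <- if (length(aux[[1]])) max(aux[[1]]) else 0
  outP <- list(); sal <- numeric(0); rad <- numeric(0)
  for (i in seq_along(polys)) {
    if (aux[[1]][i] < minSalienceFrac * salRef) next
    # a trace must have the transverse support of ONE actual fiber: thin
    # strands traced through blur halos or noise are not fibers, and a
    # profile much wider than the expected radius is an unresolvable
    # bundle of overlapping fibers whose axis angle represents neither
    if (aux[[2]][i] < minRadiusFrac * radiusUm ||
        aux[[2]][i] > maxRadiusFrac * radiusUm) next
    pieces <- .straightPieces(polys[[i]], maxResidFrac, residFloorUm)
    for (p in pieces) {
      if (polylineLength(p) < minLengthUm) next
      outP[[length(outP) + 1]] <- p
      sal <- c(sal, aux[[1]][i])
      rad <- c(rad, aux[[2]][i])
    }
  }
  if (length(outP) > 1) {
    gg <- .groupCollinear(outP, list(sal, rad))
    outP <- gg$polys; sal <- gg$aux[[1]]; rad <- gg$aux[[2]]
  }
  if (!length(outP))
    return(new("FiberSet", fibers = list(), angleDeg = numeric(0),
               salience = numeric(0), radiusUm = numeric(0)))
  fiberSet(outP,
           angleDeg = vapply(lapply(outP, .polyInterior), polylineAngle, 1.0),
           salience = sal, radiusUm = rad)
}

#' Extract fibers from an SHG image or stack
#'
#' Computes a multiscale Hessian ridge response at scales bracketing the
#' expected fiber radius, keeps the top \code{keepFraction} of pixels by
#' ridge response (default 0.06, the salience threshold of the fiber
#' analysis), skeletonizes the retained support, traces it into polylines
#' split at junction points, refines each trace to subpixel precision
#' against the ridge response, re-chains nearly collinear fragments (within
#' a slice, and for stacks also across neighbouring slices, where a tilted
#' fiber continues), and discards traces shorter than \code{minLengthUm}.
#' Each fiber's representative angle is the total-least-squares line
#' through its in-plane polyline, in degrees from the outward normal, in
#' [0, 180).
#'
#' An image with no retained support yields an empty \code{FiberSet}, not an
#' error.
#'
#' @param x an \code{ShgStack} or a 2D numeric matrix.
#' @param keepFraction fraction of pixels to keep by ridge response (0, 1].
#' @param minLengthUm minimum trace length in um (default 20, two fiber
#'   diameters).
#' @param radiusUm expected fiber radius in um (sets the filter scales).
#' @param ... passed between methods; matrices accept \code{pixelUm}
#'   (default c(1.21, 1.21)) and \code{zUm}.
#' @return A \code{FiberSet}.
#' @rdname extractFibers
#' @export
setMethod("extractFibers", "matrix",
  function(x, keepFraction = 0.06, minLengthUm = 20, radiusUm = 5, ...,
           pixelUm = c(1.21, 1.21), zUm = 0) {
    res <- .extractFragments2d(x, pixelUm, zUm, keepFraction, radiusUm)
    .fiberSetFrom(res$polys, res$aux, minLengthUm, radiusUm)
  })

#' @rdname extractFibers
#' @export
setMethod("extractFibers", "ShgStack",
  function(x, keepFraction = 0.06, minLengthUm = 20, radiusUm = 5, ...) {
    v <- x@voxelUm
    d <- dim(x@intensities)
    polys <- list(); sal <- numeric(0); rad <- numeric(0)
    for (k in seq_len(d[3])) {
      res <- .extractFragments2d(x@intensities[, , k], c(v[["y"]], v[["x"]]),
                                 (k - 1) * v[["z"]], keepFraction, radiusUm)
      polys <- c(polys, res$polys)
      sal <- c(sal, res$aux[[1]])
      rad <- c(rad, res$aux[[2]])
    }
    if (!length(polys))
      return(new("FiberSet", fibers = list(), angleDeg = numeric(0),
                 salience = numeric(0), radiusUm = numeric(0)))
    # a tilted fiber's trace continues in the neighbouring slice: chain
    # fragments across slices before filtering on length
    arr <- x@intensities
    sliceOf <- function(zu) pmin(pmax(round(zu / v[["z"]]) + 1, 1), d[3])
    pts <- do.call(rbind, lapply(polys, function(p)
      p[seq(1, nrow(p), by = 5), , drop = FALSE]))
    iy <- pmin(pmax(round(pts[, 1] / v[["y"]]) + 1, 1), d[1])
    ix <- pmin(pmax(round(pts[, 2] / v[["x"]]) + 1, 1), d[2])
    onFiber <- stats::median(arr[cbind(iy, ix, sliceOf(pts[, 3]))])
    bridgeOk3d <- function(pa, pb) {
      t <- seq(0, 1, length.out = 11)
      yy <- (pa[1] + t * (pb[1] - pa[1])) / v[["y"]] + 1
      xx <- (pa[2] + t * (pb[2] - pa[2])) / v[["x"]] + 1
      ka <- sliceOf(pa[3]); kb <- sliceOf(pb[3])
      va <- .bilinear(arr[, , ka], yy, xx)
      vb <- if (kb != ka) .bilinear(arr[, , kb], yy, xx) else va
      mean(pmax(va, vb)) >= 0.4 * onFiber
    }
    res <- .mergeToFixpoint(polys, list(sal, rad),
                            gapUm = max(8, 4 * radiusUm), maxTurnDeg = 30,
                            dzMaxUm = 1.1 * v[["z"]],
                            gapFarUm = 10 * radiusUm, bridgeOk = bridgeOk3d)
    .fiberSetFrom(res$polys, res$aux, minLengthUm, radiusUm)
  })

#' Classify fiber orientations into perpendicular and parallel windows
#'
#' Perpendicular fibers have angles within \code{perpHalfwidthDeg} of the
#' outward normal (0 +- hw and 180 -+ hw degrees); parallel fibers lie
#' within \code{parHalfwidthDeg} of 90 degrees. Window edges are inclusive
#' and the windows are disjoint, so no fiber is double-counted. The
#' orientation distribution is called bimodal when both windows hold at
#' least 20\% of the fibers.
#'
#' @param f a \code{FiberSet} (possibly empty) or a numeric vector of angles
#'   in degrees.
#' @param perpHalfwidthDeg,parHalfwidthDeg window half-widths (default 5).
#' @param binWidthDeg histogram bin width in degrees (default 5).
#' @return An \code{OrientationSummary}; with no fibers the percentages and
#'   bimodality are \code{NA}.
#' @export
classifyOrientation <- function(f, perpHalfwidthDeg = 5, parHalfwidthDeg = 5,
                                binWidthDeg = 5) {
  th <- if (is(f, "FiberSet")) f@angleDeg else as.numeric(f)
  th <- th %% 180
  n <- length(th)
  breaks <- seq(0, 180, by = binWidthDeg)
  if (n == 0) {
    h <- rep(0, length(breaks) - 1)
    names(h) <- sprintf("[%g,%g)", breaks[-length(breaks)], breaks[-1])
    return(new("OrientationSummary", histogram = h,
               binWidthDeg = binWidthDeg, pctPerpendicular = NA_real_,
               pctParallel = NA_real_, nFibers = 0L, bimodal = NA))
  }
  counts <- table(cut(th, breaks = breaks, right = FALSE,
                      include.lowest = TRUE))
  h <- as.numeric(counts)
  names(h) <- sprintf("[%g,%g)", breaks[-length(breaks)], breaks[-1])
  perp <- th <= perpHalfwidthDeg | th >= 180 - perpHalfwidthDeg
  par <- abs(th - 90) <= parHalfwidthDeg
  pctPerp <- 100 * sum(perp) / n
  pctPar <- 100 * sum(par) / n
  new("OrientationSummary", histogram = h, binWidthDeg = binWidthDeg,
      pctPerpendicular = pctPerp, pctParallel = pctPar,
      nFibers = as.integer(n), bimodal = pctPerp >= 20 && pctPar >= 20)
}

#' Per-ROI orientation analysis
#'
#' Samples regions of interest (default four of 600 x 450 um with a 150 px
#' boundary margin), extracts and classifies fibers inside each, and pools
#' the window percentages across ROIs as mean +- sd.
#'
#' @param s an \code{ShgStack} (preprocessed).
#' @param nRois number of ROIs (default 4).
#' @param sizeUm ROI size (y, x) in um; default 600 x 450.
#' @param marginPx boundary margin in pixels (default 150).
#' @param seed integer seed for ROI placement.
#' @param keepFraction,minLengthUm,radiusUm passed to
#'   \code{\link{extractFibers}}.
#' @param perpHalfwidthDeg,parHalfwidthDeg,binWidthDeg passed to
#'   \code{\link{classifyOrientation}}.
#' @return list with \code{perRoi} (list of \code{OrientationSummary}),
#'   \code{rois}, and \code{pooled} (data.frame of mean and sd of the two
#'   percentages across ROIs).
#' @export
roiOrientationAnalysis <- function(s, nRois = 4L, sizeUm = c(600, 450),
                                   marginPx = 150L, seed = NULL,
                                   keepFraction = 0.06, minLengthUm = 20,
                                   radiusUm = 5, perpHalfwidthDeg = 5,
                                   parHalfwidthDeg = 5, binWidthDeg = 5) {
  rois <- sampleRois(s, n = nRois, sizeUm = sizeUm, marginPx = marginPx,
                     seed = seed)
  perRoi <- lapply(seq_len(nrow(rois)), function(i) {
    sub <- cropStack(s, rois$y0[i], rois$x0[i], rois$h[i], rois$w[i])
    classifyOrientation(extractFibers(sub, keepFraction = keepFraction,
                                      minLengthUm = minLengthUm,
                                      radiusUm = radiusUm),
                        perpHalfwidthDeg, parHalfwidthDeg, binWidthDeg)
  })
  pp <- vapply(perRoi, function(o) o@pctPerpendicular, 1.0)
  pl <- vapply(perRoi, function(o) o@pctParallel, 1.0)
  if (nRois == 1L)
    warning("pooled sd over a single ROI is degenerate; reported as 0")
  pooled <- data.frame(
    metric = c("pct_perpendicular", "pct_parallel"),
    mean = c(mean(pp, na.rm = TRUE), mean(pl, na.rm = TRUE)),
    sd = c(if (nRois > 1) stats::sd(pp, na.rm = TRUE) else 0,
           if (nRois > 1) stats::sd(pl, na.rm = TRUE) else 0))
  list(perRoi = perRoi, rois = rois, pooled = pooled)
}
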