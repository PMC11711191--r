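test_that("two orthogonal fibers through a point form one crossing", {
  f <- fiberSet(list(rbind(c(0, 50, 0), c(100, 50, 0)),
                     rbind(c(50, 0, 0), c(50, 100, 0))),
                radiusUm = 5)
  res <- detectCrossings(f)
  expect_identical(res@crossingCount, 1L)
  expect_equal(res@crossingLocations[1, c("y", "x")], c(y = 50, x = 50),
               tolerance = 1)
})

test_that("separated parallel fibers never cross", {
  f <- fiberSet(list(rbind(c(0, 0, 0), c(100, 0, 0)),
                     rbind(c(0, 30, 0), c(100, 30, 0))),
                radiusUm = 5)
  expect_identical(detectCrossings(f)@crossingCount, 0L)
  # transversal but out of reach in z
  g <- fiberSet(list(rbind(c(0, 50, 0), c(100, 50, 0)),
                     rbind(c(50, 0, 40), c(50, 100, 40))),
                radiusUm = 5)
  expect_identical(detectCrossings(g)@crossingCount, 0L)
})

test_that("near-parallel contact counts as bundling, not crossing", {
  # 10 degrees apart, touching: below the 15-degree transversality threshold
  f <- fiberSet(list(rbind(c(50, 0, 0), c(50, 100, 0)),
                     rbind(c(41.2, 0, 0), c(58.8, 100, 0))),
                radiusUm = 5)
  expect_identical(detectCrossings(f)@crossingCount, 0L)
})

test_that("missing radii without an explicit contact distance error out", {
  f <- fiberSet(list(rbind(c(0, 0, 0), c(10, 0, 0)),
                     rbind(c(0, 5, 0), c(10, 5, 0))))
  expect_error(detectCrossings(f), "radii")
  expect_identical(detectCrossings(f, contactDistUm = 1)@crossingCount, 0L)
})

test_that("detection equals the exhaustive pairwise oracle on random sets", {
  for (rep in 1:20) {
    tr <- phantomTruth(nFibers = 5L + (rep * 7L) %% 26L,
                       seed = 3000L + rep)
    g <- genFiberStack(tr, shapePx = c(120L, 120L, 8L))
    expect_identical(detectCrossings(g$fibers)@crossingCount,
                     as.integer(oracleCrossingCount(g$fibers)))
  }
})

test_that("crossing counts ignore fiber enumeration order", {
  tr <- phantomTruth(nFibers = 25L, seed = 77L)
  g <- genFiberStack(tr, shapePx = c(140L, 140L, 6L))
  f <- g$fibers
  idx <- rev(seq_len(nFibers(f)))
  frev <- fiberSet(fibers(f)[idx], angleDeg = fiberAngles(f)[idx],
                   salience = f@salience[idx], radiusUm = f@radiusUm[idx])
  expect_identical(detectCrossings(f)@crossingCount,
                   detectCrossings(frev)@crossingCount)
})

test_that("density arithmetic follows the stated ROI geometry", {
  # one crossing at the centre of a 200 x 200 px ROI at 1.21 um/px, 100 um
  ctr <- 100 * 1.21
  f <- fiberSet(list(rbind(c(ctr, 0, 50), c(ctr, 2 * ctr, 50)),
                     rbind(c(0, ctr, 50), c(2 * ctr, ctr, 50))),
                radiusUm = 5)
  res <- crossingDensity(f)
  expect_equal(res@roiVolumeUm3, 5856400)
  expect_identical(res@crossingCount, 1L)
  expect_equal(res@densityPerUm3, 1 / 5856400)
  # an empty fiber set has zero density, defined volume
  e <- crossingDensity(fiberSet(list(), radiusUm = numeric(0)))
  expect_identical(e@crossingCount, 0L)
  expect_equal(e@densityPerUm3, 0)
  expect_error(crossingDensity(f, depthUm = 0), "volume|degenerate")
})

test_that("counts are additive over adjacent half-open ROI boxes", {
  tr <- phantomTruth(nFibers = 30L, seed = 31L)
  g <- genFiberStack(tr, shapePx = c(200L, 200L, 8L))
  f <- g$fibers
  half <- c(100, 200)
  left <- crossingDensity(f, roiPx = half, depthUm = 100,
                          originUm = c(0, 0, 0))
  right <- crossingDensity(f, roiPx = half, depthUm = 100,
                           originUm = c(100 * 1.21, 0, 0))
  whole <- crossingDensity(f, roiPx = c(200, 200), depthUm = 100)
  expect_identical(whole@crossingCount,
                   left@crossingCount + right@crossingCount)
})

test_that("density halves when the ROI depth doubles", {
  tr <- phantomTruth(nFibers = 20L, plantedCrossingCount = 5L,
                     fiberLengthUm = 150, seed = 41L)
  g <- genFiberStack(tr, shapePx = c(220L, 220L, 8L), retryBudget = 800L)
  d1 <- crossingDensity(g$fibers, depthUm = 100)
  d2 <- crossingDensity(g$fibers, depthUm = 200)
  expect_identical(d1@crossingCount, d2@crossingCount)  # all fibers inside
  expect_equal(d2@densityPerUm3, d1@densityPerUm3 / 2, tolerance = 1e-12)
})

test_that("the four-ROI wrapper reports mean and sd of densities", {
  tr <- phantomTruth(nFibers = 24L, plantedCrossingCount = 6L,
                     fiberLengthUm = 150, seed = 51L)
  g <- genFiberStack(tr, shapePx = c(260L, 260L, 8L), retryBudget = 800L)
  res <- crossingDensityRois(g$fibers, nRois = 4L, roiPx = c(120, 120),
                             depthUm = 85, seed = 2L)
  expect_length(res$perRoi, 4L)
  dens <- vapply(res$perRoi, function(r) r@densityPerUm3, 1.0)
  expect_equal(res$densityMean, mean(dens))
  expect_equal(res$densitySd, sd(dens))
})
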