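test_that("layered phantoms honor requested thicknesses exactly when flat", {
  tr <- phantomTruth(layerThicknessMm = c(SC = 0.39, VE = 0.05, D = 0.8),
                     boundaryUndulationMm = 0)
  img <- genLayerImage(tr, widthPx = 120L, pixelSizeMm = 0.01)
  lab <- layerLabels(img)
  scRuns <- colSums(lab == 1L)
  expect_true(all(scRuns == round(0.39 / 0.01)))
  expect_true(all(colSums(lab == 2L) == round(0.05 / 0.01)))
  expect_true(all(colSums(lab == 3L) == round(0.8 / 0.01)))
  # runs are contiguous and ordered SC above VE above D
  j <- 7L
  runs <- rle(lab[, j])
  expect_identical(runs$values[runs$values != 0L], c(1L, 2L, 3L))
})

test_that("single-layer phantom: only dermis pixels", {
  tr <- phantomTruth(layerThicknessMm = c(SC = 0, VE = 0, D = 1),
                     boundaryUndulationMm = 0)
  img <- genLayerImage(tr, widthPx = 50L, pixelSizeMm = 0.01)
  lab <- layerLabels(img)
  expect_true(all(colSums(lab == 3L) == 100L))
  expect_true(all(colSums(lab == 1L) == 0L))
  expect_true(all(colSums(lab == 2L) == 0L))
})

test_that("undulating boundaries average out over full periods", {
  tr <- phantomTruth(layerThicknessMm = c(SC = 0.5, VE = 0.2, D = 0.8),
                     boundaryUndulationMm = 0.1, seed = 7L)
  img <- genLayerImage(tr, widthPx = 1000L, pixelSizeMm = 0.01)
  sc <- colSums(layerLabels(img) == 1L) * 0.01
  expect_lt(abs(mean(sc) - 0.5), 0.01)
})

test_that("oversized layers trigger a sizing error naming the layer", {
  tr <- phantomTruth(layerThicknessMm = c(SC = 0.1, VE = 0.1, D = 5),
                     boundaryUndulationMm = 0)
  expect_error(genLayerImage(tr, widthPx = 20L, pixelSizeMm = 0.01,
                             heightPx = 100L), "D")
})

test_that("phantom generation is deterministic under a fixed seed", {
  tr <- phantomTruth(nFibers = 15L, seed = 42L)
  a <- genFiberStack(tr, shapePx = c(96L, 96L, 4L))
  b <- genFiberStack(tr, shapePx = c(96L, 96L, 4L))
  expect_identical(intensities(a$stack), intensities(b$stack))
  expect_identical(fiberAngles(a$truth), fiberAngles(b$truth))
  img1 <- genLayerImage(phantomTruth(seed = 5L), 60L, 0.01)
  img2 <- genLayerImage(phantomTruth(seed = 5L), 60L, 0.01)
  expect_identical(layerLabels(img1), layerLabels(img2))
})

test_that("degenerate mixture puts every angle in the perpendicular window", {
  tr <- phantomTruth(nFibers = 50L, mixtureWeights = c(1, 0, 0), seed = 3L)
  g <- genFiberStack(tr, shapePx = c(128L, 128L, 6L))
  a <- fiberAngles(g$truth)
  expect_length(a, 50L)
  expect_true(all(a <= 5 | a >= 175))
})

test_that("empirical mixture fractions converge to the weights", {
  withr::with_seed(3L, {
    a <- sampleMixtureAngles(400L, c(0.25, 0.25, 0.5))
  })
  expect_lt(abs(mean(a <= 5 | a >= 175) - 0.25), 0.05)
  withr::with_seed(11L, {
    b <- sampleMixtureAngles(1000L, c(0.3, 0.3, 0.4))
  })
  se <- sqrt(0.3 * 0.7 / 1000)
  expect_lt(abs(mean(b <= 5 | b >= 175) - 0.3), 3 * se)
  expect_lt(abs(mean(abs(b - 90) <= 5) - 0.3), 3 * se)
})

test_that("noise-free rendering of the emitted truth reproduces the stack", {
  tr <- phantomTruth(nFibers = 12L, noiseSigma = 0, seed = 9L)
  g <- genFiberStack(tr, shapePx = c(100L, 100L, 5L),
                     psfSigmaUm = c(0, 0, 0))
  mask <- renderFiberSet(g$fibers, c(100L, 100L, 5L))
  expect_identical(intensities(g$stack) > 0, mask == 1L)
})

test_that("planted crossings match the exhaustive pairwise oracle", {
  tr <- phantomTruth(nFibers = 20L, plantedCrossingCount = 6L,
                     fiberLengthUm = 150, seed = 21L)
  g <- genFiberStack(tr, shapePx = c(220L, 220L, 8L), retryBudget = 800L)
  expect_identical(g$truth@plantedCrossingCount,
                   as.integer(oracleCrossingCount(g$fibers)))
  expect_identical(g$truth@plantedCrossingCount, 6L)
})

test_that("paired stacks scale on-fiber intensity by the stated ratio", {
  tr <- phantomTruth(nFibers = 10L, noiseSigma = 0, seed = 4L)
  for (ratio in c(1, 2, 6)) {
    pr <- genPairedStacks(tr, intensityRatio = ratio,
                          shapePx = c(96L, 96L, 3L),
                          psfSigmaUm = c(0, 0, 0))
    von <- intensities(pr$ventral); don <- intensities(pr$dorsal)
    on <- don > 0
    expect_equal(mean(von[on]) / mean(don[on]), ratio, tolerance = 1e-12)
  }
})

test_that("scaled intensity beyond the 12-bit ceiling warns about clipping", {
  tr <- phantomTruth(nFibers = 8L, intensityScale = 600, noiseSigma = 0,
                     seed = 4L)
  expect_warning(genPairedStacks(tr, intensityRatio = 8,
                                 shapePx = c(64L, 64L, 2L)),
                 "clip")
})

test_that("phantom parameter validation rejects inconsistent settings", {
  expect_error(phantomTruth(mixtureWeights = c(0.5, 0.4, 0.3)), "sum")
  expect_error(phantomTruth(fiberAnglesDeg = c(10, 190)), "180")
  expect_error(phantomTruth(fiberRadiusUm = -1), "positive")
})
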