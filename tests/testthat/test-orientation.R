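test_that("window classification matches a hand count", {
  o <- classifyOrientation(c(0, 90, 45, 178))
  expect_equal(o@pctPerpendicular, 50)
  expect_equal(o@pctParallel, 25)
  expect_true(o@bimodal)
  expect_equal(sum(o@histogram), 4)
})

test_that("a single-mode angle set is not bimodal", {
  o <- classifyOrientation(rep(90, 30))
  expect_equal(o@pctParallel, 100)
  expect_equal(o@pctPerpendicular, 0)
  expect_false(o@bimodal)
})

test_that("windows are disjoint, edge-inclusive and never double-count", {
  th <- c(0, 5, 5.01, 85, 90, 95, 95.01, 174.99, 175, 179.9)
  o <- classifyOrientation(th)
  # by hand: perpendicular {0, 5, 175, 179.9}; parallel {85, 90, 95}
  expect_equal(o@pctPerpendicular, 40)
  expect_equal(o@pctParallel, 30)
  expect_lte(o@pctPerpendicular + o@pctParallel, 100)
})

test_that("an empty fiber set yields an explicit no-fibers summary", {
  o <- classifyOrientation(numeric(0))
  expect_identical(nFibers(o), 0L)
  expect_true(is.na(o@pctPerpendicular))
  expect_true(is.na(o@bimodal))
})

test_that("percentages ignore fiber order and intensity scale", {
  a <- c(3, 88, 45, 91, 177, 120)
  expect_equal(classifyOrientation(a)@pctParallel,
               classifyOrientation(rev(a))@pctParallel)
  m <- matrix(0, 120, 120)
  m[40:47, ] <- 600   # one horizontal tube (parallel fiber)
  f1 <- extractFibers(m, pixelUm = c(1.21, 1.21))
  f2 <- extractFibers(5 * m, pixelUm = c(1.21, 1.21))
  expect_equal(nFibers(f1), nFibers(f2))
  expect_equal(fiberAngles(f1), fiberAngles(f2), tolerance = 1e-6)
})

test_that("keepFraction = 1 keeps the whole positive-response support", {
  tp <- fiberweave:::thresholdTopPixels
  resp <- matrix(c(0, 0.2, 5, 1, 0, 3), 2)
  expect_identical(tp(resp, 1), resp > 0)
  expect_equal(sum(tp(resp, 1 / 6)), 1L)  # only the strongest pixel
})

test_that("50 parallel tubes are traced as 50 fibers at 90 degrees", {
  fs <- parallelTubeSet(50, 90)
  mask <- renderFiberSet(fs, c(320L, 320L, 5L))
  s <- shgStack(600 * mask)
  f <- extractFibers(s)
  expect_equal(nFibers(f), 50L)
  expect_true(all(abs(fiberAngles(f) - 90) <= 1))
})

test_that("traced angles match ground truth for a mixed phantom", {
  tr <- phantomTruth(nFibers = 60L, mixtureWeights = c(0.25, 0.25, 0.5),
                     seed = 17L)
  g <- genFiberStack(tr, shapePx = c(256L, 256L, 12L))
  f <- extractFibers(gaussianBlur(clipRange(g$stack)))
  expect_gt(nFibers(f), 30L)
  # match each trace to the nearest truth fiber (mean point distance)
  errs <- vapply(seq_along(fibers(f)), function(i) {
    p <- fibers(f)[[i]]
    sm <- p[seq(1, nrow(p), length.out = min(10, nrow(p))), , drop = FALSE]
    dmean <- vapply(fibers(g$fibers), function(q) {
      ev <- fiberweave:::cpp_polyline_contacts(sm, q, 1e9)
      mean(vapply(split(ev[, "dist"], ev[, "seg_a"]), min, 1.0))
    }, 1.0)
    j <- which.min(dmean)
    min(abs(fiberAngles(f)[i] - fiberAngles(g$fibers)[j]) %% 180,
        180 - abs(fiberAngles(f)[i] - fiberAngles(g$fibers)[j]) %% 180)
  }, 1.0)
  expect_gte(mean(errs <= 3), 0.9)
})

test_that("per-ROI analysis pools percentages and flags degenerate sd", {
  tr <- phantomTruth(nFibers = 120L, mixtureWeights = c(0.3, 0.3, 0.4),
                     seed = 19L)
  g <- genFiberStack(tr, shapePx = c(560L, 560L, 10L))
  s <- gaussianBlur(clipRange(g$stack))
  res <- roiOrientationAnalysis(s, nRois = 2L, sizeUm = c(250, 250),
                                marginPx = 30L, seed = 5L)
  expect_length(res$perRoi, 2L)
  expect_equal(res$pooled$metric,
               c("pct_perpendicular", "pct_parallel"))
  expect_true(all(is.finite(res$pooled$mean)))
  expect_warning(
    roiOrientationAnalysis(s, nRois = 1L, sizeUm = c(250, 250),
                           marginPx = 30L, seed = 5L),
    "degenerate")
})

test_that("an image with no signal yields an empty fiber set, not an error", {
  f <- extractFibers(matrix(0, 64, 64), pixelUm = c(1.21, 1.21))
  expect_identical(nFibers(f), 0L)
  o <- classifyOrientation(f)
  expect_identical(nFibers(o), 0L)
})
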