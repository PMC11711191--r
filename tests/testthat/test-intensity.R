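mkStack <- function(value = 100, ny = 800, nx = 800, nz = 2) {
  shgStack(array(value, dim = c(ny, nx, nz)))
}

test_that("a constant stack gives identical ROI means and zero sd", {
  s <- mkStack(100)
  rois <- sampleRois(s, n = 4L, marginPx = 20L, seed = 1L)
  r <- roiMeanIntensity(s, rois)
  expect_equal(r@perRoiMean, rep(100, 4))
  expect_equal(r@grandMean, 100)
  expect_equal(r@grandSd, 0)
})

test_that("ROI sampling honors margins, counts and non-overlap", {
  s <- mkStack(1, 5000 / 1.21, 3000 / 1.21)
  rois <- sampleRois(s, n = 10L, seed = 3L)
  expect_equal(nrow(rois), 10L)
  d <- dim(intensities(s))
  expect_true(all(rois$y0 >= 151 & rois$x0 >= 151))
  expect_true(all(rois$y0 + rois$h - 1 <= d[1] - 150))
  expect_true(all(rois$x0 + rois$w - 1 <= d[2] - 150))
  # pairwise disjoint
  for (i in 1:9) for (j in (i + 1):10) {
    sep <- abs(rois$y0[i] - rois$y0[j]) >= rois$h[1] ||
      abs(rois$x0[i] - rois$x0[j]) >= rois$w[1]
    expect_true(sep)
  }
  # ROI size honors the physical voxel size
  expect_equal(rois$h[1], round(200 / 1.21))
  expect_equal(rois$w[1], round(250 / 1.21))
  # deterministic given the seed
  expect_identical(rois, sampleRois(s, n = 10L, seed = 3L))
  expect_equal(nrow(sampleRois(s, n = 0L, seed = 1L)), 0L)
})

test_that("infeasible ROI geometry reports a placement error", {
  s <- mkStack(1, 100, 100)
  expect_error(sampleRois(s, n = 2L, marginPx = 150L, seed = 1L),
               "admissible|feasible")
})

test_that("ROI centers are uniform over the admissible region", {
  s <- mkStack(1, 420, 420, 1)
  ys <- vapply(1:400, function(k)
    sampleRois(s, n = 1L, sizeUm = c(50, 50), marginPx = 30L,
               seed = 1000L + k)$y0, 1L)
  # admissible origins are 31..(420 - 30 - 41 + 1); bin into quartiles
  br <- quantile(c(31, 420 - 30 - 41 + 1), probs = seq(0, 1, 0.25))
  counts <- table(cut(ys, breaks = br, include.lowest = TRUE))
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})

test_that("ROI means are linear in intensity and order-invariant", {
  withr::with_seed(5, {
    s <- shgStack(array(runif(400 * 400 * 2, 0, 100), dim = c(400, 400, 2)))
  })
  rois <- sampleRois(s, n = 5L, sizeUm = c(60, 60), marginPx = 20L, seed = 2L)
  r1 <- roiMeanIntensity(s, rois)
  s3 <- shgStack(3 * intensities(s))
  r3 <- roiMeanIntensity(s3, rois)
  expect_equal(r3@perRoiMean, 3 * r1@perRoiMean, tolerance = 1e-12)
  rrev <- roiMeanIntensity(s, rois[rev(seq_len(nrow(rois))), ])
  expect_equal(sort(rrev@perRoiMean), sort(r1@perRoiMean))
  expect_equal(rrev@grandMean, r1@grandMean)
})

test_that("an ROI outside the image names the offender", {
  s <- mkStack(1, 100, 100)
  bad <- data.frame(roi = 7L, y0 = 90L, x0 = 5L, h = 20L, w = 20L)
  expect_error(roiMeanIntensity(s, bad), "ROI 7")
})

test_that("identical samples contrast to fold 1 and non-significance", {
  s <- mkStack(100)
  rois <- sampleRois(s, n = 5L, marginPx = 20L, seed = 1L)
  r <- roiMeanIntensity(s, rois)
  # identical per-ROI values are degenerate but well-defined
  ct <- intensityContrast(r, r)
  expect_equal(ct$fold, 1)
  expect_identical(ct$test@stars, "ns")
})

test_that("a zero-intensity denominator is an undefined-ratio error", {
  s0 <- mkStack(0)
  s1 <- mkStack(10)
  rois <- sampleRois(s1, n = 4L, marginPx = 20L, seed = 1L)
  a <- roiMeanIntensity(s1, rois)
  b <- roiMeanIntensity(s0, rois)
  expect_error(intensityContrast(a, b), "ratio")
})

test_that("a planted two-fold pair is recovered with high significance", {
  tr <- phantomTruth(nFibers = 60L, seed = 12L)
  pr <- genPairedStacks(tr, intensityRatio = 2,
                        shapePx = c(1100L, 900L, 2L))
  rois <- sampleRois(pr$ventral, n = 10L, marginPx = 50L, seed = 13L)
  rv <- roiMeanIntensity(pr$ventral, rois)
  rd <- roiMeanIntensity(pr$dorsal, rois)
  ct <- intensityContrast(rv, rd)
  expect_gt(ct$fold, 1.5)
  expect_lt(ct$test@pValue, 0.01)
})
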