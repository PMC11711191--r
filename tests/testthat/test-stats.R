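test_that("identical samples give t = 0, p = 1 and no stars", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  r <- compareGroups(x, x)
  expect_equal(r@statistic, 0)
  expect_equal(r@pValue, 1)
  expect_identical(r@stars, "ns")
  # degenerate constant groups are handled, not an error
  rc <- compareGroups(rep(2, 5), rep(2, 5))
  expect_equal(rc@pValue, 1)
})

test_that("star thresholds are strict and monotone", {
  expect_identical(starsForP(0.05), "ns")
  expect_identical(starsForP(0.049), "*")
  expect_identical(starsForP(0.01), "*")
  expect_identical(starsForP(0.0099), "**")
  expect_identical(starsForP(0.001), "**")
  expect_identical(starsForP(0.0009), "***")
  ps <- sort(c(10^seq(-6, -0.1, length.out = 30), 0.001, 0.01, 0.05))
  ranks <- c("ns" = 0, "*" = 1, "**" = 2, "***" = 3)
  stars <- ranks[vapply(ps, starsForP, "")]
  expect_true(all(diff(stars) <= 0))
})

test_that("the comparison is symmetric up to the sign of the statistic", {
  withr::with_seed(4, {
    a <- rnorm(12, 5); b <- rnorm(12, 6)
  })
  r1 <- compareGroups(a, b)
  r2 <- compareGroups(b, a)
  expect_equal(r1@pValue, r2@pValue)
  expect_equal(r1@statistic, -r2@statistic)
})

test_that("clearly separated groups earn three stars", {
  withr::with_seed(6, {
    a <- rnorm(10, 200, 10); b <- rnorm(10, 100, 10)
  })
  r <- compareGroups(a, b)
  expect_identical(r@stars, "***")
  expect_lt(r@pValue, 0.001)
})

test_that("Levene failure triggers the Welch variant, recorded in the name", {
  withr::with_seed(8, {
    a <- rnorm(30, 0, 1); b <- rnorm(30, 0, 12)
  })
  r <- compareGroups(a, b)
  expect_false(r@varianceHomogeneous)
  expect_match(r@testName, "Welch")
})

test_that("undersized groups are rejected", {
  expect_error(compareGroups(c(1, 2), c(1, 2, 3)), "n >= 3")
})

test_that("null type-I error stays near the nominal level", {
  withr::with_seed(10, {
    rej <- vapply(1:300, function(k)
      compareGroups(rnorm(10), rnorm(10))@pValue < 0.05, TRUE)
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("report bundles assemble the requested sections", {
  tr <- phantomTruth(layerThicknessMm = c(SC = 0.39, VE = 0.05, D = 0.8),
                     boundaryUndulationMm = 0)
  prof <- stripThickness(genLayerImage(tr, 50L, 0.01))
  rep1 <- reportBundle(thickness = list(prof))
  expect_s3_class(rep1, "ReportSet")
  expect_named(rep1, "thickness")
  expect_equal(nrow(rep1$thickness), 1L)
  expect_error(reportBundle(), "at least one")

  # orientation section: four ROIs at ~25/25 are not significantly different
  mkSummary <- function(nPerp, nPar) {
    classifyOrientation(c(rep(0, nPerp), rep(90, nPar),
                          rep(45, 100 - nPerp - nPar)))
  }
  orient <- list(perRoi = list(mkSummary(24, 25), mkSummary(26, 25),
                               mkSummary(25, 24), mkSummary(25, 26)),
                 pooled = data.frame(metric = c("pct_perpendicular",
                                                "pct_parallel"),
                                     mean = c(25, 25), sd = c(2, 2)))
  s <- shgStack(array(100, dim = c(60, 60, 1)))
  rois <- sampleRois(s, n = 4L, sizeUm = c(20, 20), marginPx = 2L, seed = 1L)
  ri <- roiMeanIntensity(s, rois)
  crossing <- crossingDensity(fiberSet(list(), radiusUm = numeric(0)))
  full <- reportBundle(thickness = list(prof),
                       intensity = list(a = ri, b = ri),
                       orientation = orient,
                       crossings = crossing)
  expect_setequal(names(full),
                  c("thickness", "intensity", "orientation", "crossings"))
  expect_identical(full$orientation$comparison_stars[1], "ns")
  expect_equal(attr(full, "comparisons"), 2L)
})

test_that("report tables write deterministically", {
  tr <- phantomTruth(boundaryUndulationMm = 0)
  prof <- stripThickness(genLayerImage(tr, 30L, 0.01))
  rep1 <- reportBundle(thickness = list(prof))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeTables(rep1, d1)
  writeTables(rep1, d2)
  for (fn in list.files(d1)) {
    expect_identical(readLines(file.path(d1, fn)),
                     readLines(file.path(d2, fn)))
  }
})
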