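test_that("clipping bounds the range and leaves interior values alone", {
  s <- shgStack(array(c(4095, 1234, 0, 50), dim = c(2, 2, 1)))
  out <- intensities(clipRange(s))
  expect_equal(out[1, 1, 1], 4000)
  expect_equal(out[2, 1, 1], 1234)
  withr::with_seed(1, {
    m <- matrix(runif(64 * 64, 0, 8000), 64)
  })
  clipped <- clipRange(m, 0, 4000)
  expect_identical(sum(clipped > 4000), 0L)
  expect_identical(clipped[m <= 4000], m[m <= 4000])
  log <- processingLog(clipRange(s, 0, 4000))
  expect_equal(log[[length(log)]]$op, "clip_range")
})

test_that("blur with sigma zero is the identity; constants are invariant", {
  m <- matrix(rnorm(100, 50), 10)
  expect_identical(gaussianBlur(m, 0), m)
  const <- matrix(7, 20, 20)
  expect_equal(gaussianBlur(const, 0.5), const, tolerance = 1e-12)
  expect_error(gaussianBlur(m, -1), "non-negative")
})

test_that("a delta impulse blurs to the normalized sampled Gaussian", {
  m <- matrix(0, 21, 21); m[11, 11] <- 1
  out <- gaussianBlur(m, 0.5)
  # independent evaluation: k(x) = exp(-x^2 / (2 * 0.25)), normalized
  x <- -2:2
  k <- exp(-x^2 / 0.5); k <- k / sum(k)
  expect_equal(out[11, 11], k[3]^2, tolerance = 1e-12)
  expect_equal(out[11, 12], k[3] * k[4], tolerance = 1e-12)
  expect_equal(out[12, 12], k[4]^2, tolerance = 1e-12)
  # total intensity conserved for interior-supported images
  expect_equal(sum(out), 1, tolerance = 1e-3)
})

test_that("rolling ball removes flat background completely", {
  expect_equal(rollingBallSubtract(matrix(123.4, 50, 50), 10),
               matrix(0, 50, 50), tolerance = 1e-12)
})

test_that("a single-pixel spike survives the rolling ball", {
  m <- matrix(0, 100, 100); m[50, 50] <- 1000
  out <- rollingBallSubtract(m, 40)
  expect_gt(out[50, 50], 995)
})

test_that("rolling ball equals the brute-force opening oracle", {
  withr::with_seed(7, {
    for (r in c(5, 11)) {
      m <- matrix(sample(0:4095, 48 * 48, replace = TRUE) * 1.0, 48)
      expect_equal(rollingBallBackground(m, r),
                   oracleRollingBallBackground(m, r), tolerance = 1e-9)
    }
  })
})

test_that("background estimation is anti-extensive and idempotent", {
  withr::with_seed(8, {
    m <- matrix(runif(64 * 64, 0, 4000), 64)
  })
  bg <- rollingBallBackground(m, 12)
  expect_true(all(bg <= m + 1e-9))
  expect_equal(rollingBallBackground(bg, 12), bg, tolerance = 1e-9)
  out <- rollingBallSubtract(m, 12)
  expect_true(all(out <= m + 1e-9))
  expect_true(all(out >= 0))
  expect_error(rollingBallSubtract(matrix(0, 10, 10), 40), "extent")
})

test_that("the processing chain applies clip, blur, ball in order", {
  withr::with_seed(2, {
    s <- shgStack(array(runif(40 * 40 * 2, 0, 5000), dim = c(40, 40, 2)))
  })
  out <- processStack(s, ballRadiusPx = 10)
  ops <- vapply(processingLog(out), function(e) e$op, "")
  expect_identical(ops, c("clip_range", "gaussian_blur",
                          "rolling_ball_subtract"))
  # identical to applying the stages by hand
  manual <- rollingBallSubtract(gaussianBlur(clipRange(s)), 10)
  expect_equal(intensities(out), intensities(manual), tolerance = 1e-12)
  expect_true(max(intensities(out)) <= 4000)
})

test_that("all three stages are shift-equivariant on interior pixels", {
  withr::with_seed(3, {
    m <- matrix(runif(60 * 60, 0, 4000), 60)
  })
  shift <- function(x, dy, dx) {
    out <- matrix(0, nrow(x), ncol(x))
    out[(1 + dy):nrow(x), (1 + dx):ncol(x)] <-
      x[1:(nrow(x) - dy), 1:(ncol(x) - dx)]
    out
  }
  core <- 25:35
  for (f in list(function(z) clipRange(z, 0, 2000),
                 function(z) gaussianBlur(z, 0.5),
                 function(z) rollingBallSubtract(z, 6))) {
    a <- f(shift(m, 2, 3))[core + 2, core + 3]
    b <- f(m)[core, core]
    expect_equal(a, b, tolerance = 1e-9)
  }
})
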