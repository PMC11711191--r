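test_that("constant-thickness phantoms are recovered exactly", {
  tr <- phantomTruth(layerThicknessMm = c(SC = 1.8, VE = 0.42, D = 5.4),
                     boundaryUndulationMm = 0)
  img <- genLayerImage(tr, widthPx = 200L, pixelSizeMm = 0.01)
  s <- thicknessSummary(stripThickness(img))
  expect_equal(s$mean_mm, c(1.80, 0.42, 5.40), tolerance = 1e-12)
  expect_equal(s$sd_mm, c(0, 0, 0))
})

test_that("empty columns contribute zero thickness, not gaps", {
  lab <- matrix(0L, 20, 5)
  lab[3:6, 2] <- 1L   # SC in column 2 only
  img <- layerImage(lab, 0.01)
  p <- stripThickness(img)
  expect_identical(p@perStripMm$SC, c(0, 0.04, 0, 0, 0))
  expect_length(p@perStripMm$D, 5L)
})

test_that("an all-background image is an error", {
  img <- layerImage(matrix(0L, 10, 10), 0.01)
  expect_error(stripThickness(img), "foreground")
})

test_that("sinusoidal undulation yields the closed-form sd", {
  tr <- phantomTruth(layerThicknessMm = c(SC = 0.5, VE = 0.3, D = 1),
                     boundaryUndulationMm = 0.1, seed = 7L)
  img <- genLayerImage(tr, widthPx = 1000L, pixelSizeMm = 0.01)
  s <- thicknessSummary(stripThickness(img))
  sc <- s[s$layer == "SC", ]
  expect_lt(abs(sc$mean_mm - 0.5), 0.01)
  expect_lt(abs(sc$sd_mm - 0.1 / sqrt(2)), 0.1 * 0.1 / sqrt(2))
})

test_that("layer pixel counts and background are conserved per column", {
  tr <- phantomTruth(boundaryUndulationMm = 0.1, seed = 2L)
  img <- genLayerImage(tr, widthPx = 80L, pixelSizeMm = 0.01)
  lab <- layerLabels(img)
  counts <- colSums(lab == 1L) + colSums(lab == 2L) + colSums(lab == 3L) +
    colSums(lab == 0L)
  expect_true(all(counts == nrow(lab)))
})

test_that("thickness scales exactly with pixel size", {
  lab <- layerLabels(genLayerImage(phantomTruth(boundaryUndulationMm = 0.05,
                                                seed = 3L),
                                   60L, 0.01))
  p1 <- stripThickness(layerImage(lab, 0.01))
  p2 <- stripThickness(layerImage(lab, 0.02))
  for (l in c("SC", "VE", "D"))
    expect_equal(p2@perStripMm[[l]], 2 * p1@perStripMm[[l]],
                 tolerance = 1e-12)
})

test_that("strips follow the stored surface normal orientation", {
  tr <- phantomTruth(layerThicknessMm = c(SC = 0.3, VE = 0.1, D = 0.5),
                     boundaryUndulationMm = 0)
  img <- genLayerImage(tr, widthPx = 40L, pixelSizeMm = 0.01)
  rot <- layerImage(t(layerLabels(img)), 0.01, normalAxis = "x",
                    meta = sampleMetadata(img))
  expect_equal(thicknessSummary(stripThickness(rot)),
               thicknessSummary(stripThickness(img)))
})

test_that("the thickness table mirrors site values and flags duplicates", {
  mk <- function(surface, dist, th) {
    tr <- phantomTruth(layerThicknessMm = th, boundaryUndulationMm = 0)
    stripThickness(genLayerImage(tr, 50L, 0.01,
                                 meta = sampleMeta(surface, dist)))
  }
  p1 <- mk("dorsal", 3, c(SC = 0.39, VE = 0.05, D = 0.8))
  p2 <- mk("ventral", 27, c(SC = 0.29, VE = 0.50, D = 2.4))
  tab <- thicknessTable(list(p1, p2))
  expect_equal(nrow(tab), 2L)
  drow <- tab[tab$surface == "dorsal", ]
  expect_equal(drow$distance_cm, 3)
  expect_equal(drow$SC_mm, 0.39, tolerance = 1e-12)
  expect_equal(drow$VE_mm, 0.05, tolerance = 1e-12)
  expect_equal(drow$D_mm, 0.8, tolerance = 1e-12)
  expect_match(drow$SC, "0.39")
  # two distinct distances, identical values -> two rows
  p3 <- mk("dorsal", 81, c(SC = 0.39, VE = 0.05, D = 0.8))
  expect_equal(nrow(thicknessTable(list(p1, p3))), 2L)
  # duplicate site keys are an aggregation error
  expect_error(thicknessTable(list(p1, p1)), "duplicate")
})

test_that("an empty layer is reported as zero, not dropped", {
  tr <- phantomTruth(layerThicknessMm = c(SC = 0.2, VE = 0, D = 0.4),
                     boundaryUndulationMm = 0)
  tab <- thicknessTable(stripThickness(genLayerImage(tr, 30L, 0.01)))
  expect_equal(tab$VE_mm, 0)
  expect_equal(tab$VE_sd_mm, 0)
})
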