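# fiberweave

Quantitative analysis of thick, collagen-rich skin from histology and
second-harmonic-generation (SHG) microscopy, built for the kind of question
posed by muscular-hydrostat skin (the elephant trunk is the motivating
system): how can one tissue be both armored and flexible? The package
quantifies the three structural signatures behind that question:

* **Layer morphometry** — stratum corneum (SC), viable epidermis (VE) and
  dermis (D) thickness profiles from labeled histology sections. Each
  one-pixel-wide strip contributes thickness = (labeled pixels) × pixel
  size, and sites are tabulated as mean ± sd.
* **Collagen fiber orientation** — per-fiber in-plane angles θ ∈ [0°, 180°)
  measured from the skin's outward normal, classified into a
  *perpendicular* window (0 ± 5° and 180 ∓ 5°) and a *parallel* window
  (90 ± 5°), with a bimodality call when both windows hold ≥ 20% of
  fibers. Fibers are extracted with a multiscale Hessian ridge filter, a
  salience threshold keeping the top 6% of pixels by response,
  skeletonization, subpixel centerline refinement, fragment chaining and
  per-fiber grouping; the representative angle is the total-least-squares
  line through the trace.
* **Fiber entanglement** — crossings between distinct fibers, defined as
  closest approach within the sum of the two radii at a local tangent
  angle ≥ 15°, counted in a half-open 200 × 200 px × 100 µm ROI and
  reported per µm³.

Supporting stages reproduce the standard SHG preprocessing (clip to
(0, 4000), Gaussian blur σ = 0.5 px, rolling-ball background subtraction
with radius 40 px, implemented as exact grayscale opening by a spherical
cap), ROI intensity quantification (ten 200 × 250 µm ROIs, 150 px margins)
with dorsal-vs-ventral fold-change contrasts, and the statistical recipe
(Shapiro–Wilk and Levene diagnostics, then a two-sample t-test with stars
at p < 0.05 / 0.01 / 0.001).

Because raw imaging data is scarce, the package ships a synthetic phantom
generator (`phantomTruth()`, `genLayerImage()`, `genFiberStack()`,
`genPairedStacks()`) that emits exact ground truth — layer thicknesses,
per-fiber angles, planted crossing counts, planted intensity ratios — so
every stage is verifiable end to end. See the methods vignette
(`vignettes/fiberweave-methods.Rmd`) for the model details, parameter
choices and limitations.

## Worked example

Layer thickness from a phantom of the dorsal trunk root (SC 1.8 mm,
VE 0.42 mm, D 5.4 mm, 0.15 mm boundary undulation):

```r
library(fiberweave)
tr <- phantomTruth(layerThicknessMm = c(SC = 1.8, VE = 0.42, D = 5.4),
                   boundaryUndulationMm = 0.15, seed = 7)
img <- genLayerImage(tr, widthPx = 1000, pixelSizeMm = 0.01,
                     meta = sampleMeta("dorsal", 133))
thicknessTable(stripThickness(img))[, c("surface", "distance_cm", "SC", "VE", "D")]
#>   surface distance_cm         SC          VE          D
#> 1  dorsal         133 1.8 ± 0.11 0.42 ± 0.11 5.4 ± 0.11
```

The recovered means equal the generator settings; the ± 0.11 mm spread is
the sinusoidal boundary's closed-form sd (amplitude/√2 ≈ 0.106 mm, plus
pixel rounding).

Fiber orientation on a balanced bimodal stack (200 fibers, 25%
perpendicular / 25% parallel / 50% diffuse):

```r
g <- genFiberStack(phantomTruth(nFibers = 200,
                                mixtureWeights = c(0.25, 0.25, 0.5),
                                seed = 1),
                   shapePx = c(320, 320, 40))
f <- extractFibers(gaussianBlur(clipRange(g$stack)))
classifyOrientation(f)
#> OrientationSummary: n=225, 25.3% perpendicular, 24.9% parallel, bimodal
classifyOrientation(fiberAngles(g$truth))
#> OrientationSummary: n=200, 24.5% perpendicular, 26.5% parallel, bimodal
```

The extracted percentages track the emitted ground truth within a couple
of points, and the bimodality call — the structural signature
distinguishing trunk skin from single-orientation skin — matches.

An end-to-end run over synthesized inputs (`runPipeline(demoConfig(),
"out")`) writes the thickness table, the dorsal/ventral intensity contrast
with stars, the orientation summary and the crossing density, plus a
provenance record, and is byte-identical across runs with the same
configuration.

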