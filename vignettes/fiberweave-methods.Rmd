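---
title: "Quantifying skin architecture from histology and SHG microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying skin architecture from histology and SHG microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberweave)
```

## Scope

`fiberweave` quantifies the architecture of thick, collagen-rich skin — the
motivating system is elephant trunk skin, a muscular hydrostat whose skin
must combine armor-like protection with extreme flexibility — from two
standard inputs:

* segmented histology sections, labeled into stratum corneum (SC), viable
  epidermis (VE) and dermis (D), for layer-thickness morphometry; and
* 3D second-harmonic-generation (SHG) stacks of dermal collagen-I, for
  intensity quantification, per-fiber orientation statistics, and the
  density of fiber crossings ("entanglement") per unit volume.

Because raw microscopy data is bulky and scarce, every stage is paired with
a synthetic phantom generator that emits exact ground truth. All claims the
test suite makes are claims about those phantoms; what that does and does
not imply about real images is discussed at the end.

## Layer morphometry

A `LayerImage` holds an integer mask (0 background, 1 SC, 2 VE, 3 D) and a
physical pixel size in mm. `stripThickness()` splits the image into
one-pixel-wide strips along the outward surface normal and, per strip and
layer, multiplies the label pixel count by the pixel size. Two conventions
matter:

* counts, not runs — holes inside a layer do not reduce its thickness less
  than a genuine thinning would; the measure is total labeled pixels;
* strips with zero pixels of a layer contribute 0 mm rather than being
  dropped, so per-strip vectors stay aligned with the image width and
  missing tissue is visible in the standard deviation.

Layered phantoms (`genLayerImage()`) draw each boundary as a sinusoid with
an integer number of periods across the width and a seeded random phase, so
per-column thicknesses average to the requested mean up to pixel rounding
and have the closed-form standard deviation amplitude/√2. The default
thicknesses follow the dorsal 3 cm reference row of the bundled thickness
table (`trunkReferenceThickness()`); the default undulation amplitude of
0.15 mm reproduces a ~0.11 mm thickness standard deviation, typical of the
table's distal rows.

```{r}
tr <- phantomTruth(layerThicknessMm = c(SC = 0.39, VE = 0.05, D = 0.8),
                   boundaryUndulationMm = 0)
img <- genLayerImage(tr, widthPx = 200, pixelSizeMm = 0.01)
thicknessSummary(stripThickness(img))
```

## SHG preprocessing

`processStack()` applies, in order: intensity clipping to (0, 4000), a
Gaussian blur with σ = 0.5 px, and rolling-ball background subtraction with
a 40 px radius — the standard display/denoise/flatten recipe for SHG
stacks. Three numerical choices:

* **Rolling ball is exact grayscale opening.** The background is the
  morphological opening of each slice by a spherical-cap structuring
  function of the stated radius (erode then dilate with heights
  √(r² − d²) − r). This definition is testable: the suite checks bitwise
  agreement with a brute-force double-loop oracle, anti-extensivity
  (output ≤ input) and idempotence. Classic shrink/enlarge approximations
  trade those properties for speed; the compiled implementation here keeps
  them and remains fast enough (a 512² slice takes roughly a second).
* **Per-slice 2D, not 3D.** The z step (10.62 µm) is ~9× the in-plane
  pixel (1.21 µm), so slices are treated as independent images.
* **Floating point throughout**; quantization to integers happens only on
  TIFF export.

The blur uses a normalized sampled-Gaussian kernel with reflective
boundaries, so constants are invariant and total intensity is conserved
for interior-supported images.

## ROI intensity quantification

`sampleRois()` places ten 200 × 250 µm ROIs uniformly at random in the
admissible region (≥ 150 px from every border), rejecting overlaps; a
failed packing is restarted from scratch, which keeps placement feasible
when the ROIs are large relative to the image. Non-overlap is enforced —
the analysis would otherwise pseudo-replicate — and placement is seeded.
`roiMeanIntensity()` averages the maximum-intensity z-projection within
each ROI (per-slice analysis is available via `project = FALSE`), and
`intensityContrast()` reports the fold-change of grand means together with
a two-sample comparison.

The paired-phantom generator (`genPairedStacks()`) renders one fiber
geometry twice, scaling the on-fiber intensity of the "ventral" stack by a
stated ratio before adding identical-statistics read noise, so the planted
fold-change is exact. Recovering the planted ratio from ROI means requires
dermis-like dense collagen fill: with sparse fibers, the background share
of each ROI dilutes the measured fold toward 1. The intensity phantoms
therefore use ~45% in-plane fiber fill on a 1.7 × 1.3 mm single-slice
field, and the preprocessing chain (in particular the rolling ball)
removes the noise floor that would otherwise bias the ratio. Under those
conditions the ten-ROI procedure recovers planted folds of 2 and 6 within
a few percent, at p < 0.001.

## Fiber extraction and orientation

Angles are measured in the section plane from the skin's outward normal
(0° = perpendicular to the surface, 90° = parallel), as undirected
orientations in [0°, 180°). Extraction replaces curvelet-based salience
thresholding with an explicitly testable chain:

1. **Ridge response.** A multiscale Hessian ridge filter (scale-normalized
   negated smaller eigenvalue, maximized over scales bracketing the
   expected 5 µm fiber radius).
2. **Salience threshold.** The top 6% of image pixels ranked by ridge
   response are retained (`keepFraction = 0.06`). This is the analogue of
   keeping 6% of transform coefficients: the coefficient count of a
   redundant transform scales with the pixel count. Retaining 6% of
   response *mass* instead — an alternative reading — keeps so few pixels
   that traced fibers disintegrate, so the pixel-fraction definition is
   used. `keepFraction = 1` degenerates to the full positive-response
   support.
3. **Skeletonization and tracing.** Zhang–Suen thinning, branch splitting
   at skeleton junctions, subpixel centerline refinement against the ridge
   response, and moving-average smoothing of the refined path (pixel paths
   at oblique angles carry a staircase wiggle that would otherwise bias
   short traces).
4. **Chaining.** Where fibers cross, the ridge response dips and traces
   break; where a tilted fiber leaves a z slice its trace continues in the
   neighbouring slice. Trace ends are re-chained within and across slices
   under collinearity, lateral-offset and (for long bridges) image-signal
   constraints — a bridge must run over fiber-level intensity, never
   across dark background.
5. **Quality gates.** Traces must be ≥ 20 µm (two fiber diameters), carry
   fiber-level ridge signal (≥ 5% of the strongest trace), have the
   transverse half-width of an actual fiber (≥ 35% of the expected
   radius, measured as the image profile's half width at half maximum),
   and be straight enough to carry a single orientation (RMS transverse
   residual ≤ 1% of length); crooked chains are split at their largest
   kink and re-examined rather than discarded outright.
6. **Per-fiber grouping.** The statistics are per *fiber*, so fragments of
   one fiber must be counted once: traces with agreeing orientation, small
   mutual lateral offset, comparable depth and no substantial longitudinal
   overlap are grouped and concatenated along their common direction.
   Side-by-side traces of comparable length are left separate — they are
   distinct fibers.

The representative angle of each fiber is the total-least-squares line
through its polyline. `classifyOrientation()` counts fibers in the
perpendicular (0 ± 5°, 180 ∓ 5°) and parallel (90 ± 5°) windows — edges
inclusive, windows disjoint — and flags the distribution as bimodal when
both windows hold at least 20% of fibers. Histogram bins default to 5°;
the bin width is configurable since the original figure does not state
one.

On mixture phantoms (200 fibers per stack, 10 seeds per mixture, mixtures
from pure-perpendicular through balanced bimodal), recovered window
percentages track the emitted truth within ±5 points and the bimodality
call matches. The phantom stacks use 384 × 384 px × 40 slices (~5 fibers
per slice): at substantially higher per-slice crowding, overlapping
near-parallel fibers braid in the thresholded support and the recovered
percentages degrade — a real limitation for extremely dense tissue.

## Crossing ("entanglement") density

A crossing is defined geometrically: two distinct fibers approach within a
contact distance (default: the sum of their radii) with local in-plane
tangents at least 15° apart. Near-parallel contact below that angle is
bundling, not crossing. Contact events of one pair within a declustering
radius (2× contact distance) merge into one crossing. Self-crossings are
excluded. On straight-segment truth fibers this rule agrees exactly with
an exhaustive pairwise segment-distance oracle.

When the input fibers are *traced* rather than exact, one physical
crossing can surface through several fragment pairs; `detectCrossings()`
therefore accepts an optional `mergeRadiusUm` that collapses crossings
from different pairs within that radius (off by default, where the exact
per-pair rule applies; the stack-analysis path uses 2× the declustering
radius).

`crossingDensity()` restricts crossings to a half-open box — a 200 × 200 px
square extruded 100 µm deep, i.e. 5,856,400 µm³ at the 1.21 µm pixel —
making counts over adjacent ROIs exactly additive, and reports crossings
per µm³. Crossing phantoms plant transversally intersecting fiber pairs
(crossing angles ≥ 30°, 150 µm fibers) and rejection-sample the remaining
fibers with a clearance margin beyond the crossing rule, so no pair sits
on the contact or transversality boundary where estimation noise could
flip its status; the emitted truth records the realized count. Re-extracted
from rendered noisy stacks, planted counts are recovered within ±15% on
average across seeds.

## Statistical comparisons

`compareGroups()` follows the study recipe: Shapiro–Wilk normality per
group and Levene's test across groups are run and *recorded*, then a
two-sided two-sample t-test is always reported — pooled-variance when
Levene does not reject, Welch otherwise (the fallback the recipe leaves
unstated). Stars follow strict thresholds (*** p < 0.001, ** p < 0.01,
* p < 0.05). No multiple-testing correction is applied, matching the
original analysis; `reportBundle()` records the number of comparisons so
the reader can judge. Type-I error at n = 10 sits at the nominal 5%
within Monte-Carlo tolerance.

## Determinism, units and formats

All randomness is seeded, and seeded operations restore the caller's RNG
state. Identical seed and parameters give bit-identical phantoms and
byte-identical pipeline reports (no timestamps in any output).
Physical units are µm for image-space quantities and mm for the thickness
report; pixel indexing is half-open and ROI geometry is defined on voxel
centres at (i − 1) × voxel size. Stacks travel as multi-page 16-bit TIFFs
with a JSON sidecar carrying voxel sizes, metadata and the processing log;
masks as 8-bit single-page TIFFs. A reader refuses to guess units when no
sidecar and no explicit voxel size is given.

## Problem sizes used by the test suite

The suite and the acceptance script run entirely on synthetic phantoms:
layered masks of 400–1000 strips; orientation stacks of 384 × 384 px × 40
slices with 200 fibers; crossing stacks of 280 × 280 px × 10 slices with
36 fibers and 12 planted crossings; intensity fields of 1400 × 1100 px;
oracle checks on 64 × 64 images and ≤ 50-fiber instances. These sizes were
chosen as the smallest at which each estimator's operating regime (ROI
margins, salience budget, fill fraction) matches the full-scale analysis.

## Known limitations

* Phantom fibers are straight with bounded out-of-plane tilt (≤ 10°);
  strongly curved or wavy collagen is not emulated, and the
  straightness-based quality gates would split it into shorter pieces.
* The salience threshold is a fixed fraction of image pixels; images much
  emptier or much denser than the calibration regime shift the effective
  sensitivity (noise-ridge traces are suppressed by the salience, radius
  and straightness gates, but the gates are relative, not absolute).
* Passing phantom tests bounds algorithmic error, not biological or
  acquisition variability: real SHG adds depth-dependent attenuation,
  speckle, and unsegmented non-collagen signal that the generator does not
  model.
* The outward normal must be supplied (by the generator or in image
  metadata); there is no automatic surface detection.
* "Entanglement" here is crossing density as operationalized above, not a
  topological linking measure.
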