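---
title: "Measuring nerve-fiber networks: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring nerve-fiber networks: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nervemorph)
```

# The measurement problem

A DAB-developed nerve stain shows fibers as dark filaments, roughly 3–8 µm
thick, branching across a bright tissue background. Four quantities
summarize such a network per field of view: the positive area fraction
(%), the density of branching points (/mm²), the total centerline length
of the network (mm), and the mean fiber thickness (µm), defined as the
network's foreground area divided by its centerline length. Group
comparisons are then mean ± SEM with two-tailed two-sample t-tests, and
the relative abundance of two stains is the ratio of their group-mean
positive areas.

`nervemorph` implements this chain as deterministic, seeded, fully
configurable code, and validates it end-to-end on synthetic images with
exact ground truth.

# The processing model

Every stage consumes and produces a `CalibratedImage` (intensities in
[0, 1] plus µm/px); binary stages use `BinaryMask` and `SkeletonImage`.
The stage order is fixed: flatten → top-hat → threshold → artifact
removal → hole filling → thinning → spur pruning → branch points →
summary.

**Polarity.** All operators assume bright signal. `normalizeAndOrient`
scales 8/16-bit integers to [0, 1] and inverts when the stain is dark,
which it detects by the median lying above the midpoint of the intensity
range (the stain occupies a minority of pixels). Inversion happens only
here, so no later operator needs a polarity convention.

**Illumination flattening.** Shading and diffuse background are removed
in one step: a morphological opening with a disk much larger than any
fiber (default diameter 50 px; preset 31 px ≈ 5× the fiber width) is a
background estimate that cannot contain the fibers themselves; it is
subtracted and the result re-clipped. A flat image maps to zero.

**Top-hat.** The white top-hat (image minus its opening) with a disk of
radius ~2× the fiber width (default 8 px; preset 12 px) keeps structures
narrower than the element — the fibers — and suppresses wider ones. The
output is pointwise ≤ the input by construction.

**Adaptive local-mean threshold.** A pixel is foreground iff its
intensity strictly exceeds the mean of its w × w neighborhood plus an
offset constant; w defaults to 15. Ties go to background, which makes the
constant-image case unambiguous. The local mean uses symmetric-reflect
padding, so border rows are compared against a plausible neighborhood.
The rule is invariant to adding a constant to the image, and masks are
nested in the offset.

The offset is the single biggest free parameter of the chain. The preset
value 0.12 is calibrated from first principles, not fitted: background
false positives occur where noise exceeds the offset, so with noise s.d.
σ = 0.05 an offset of 2.4 σ leaves ≈ 0.8 % of background pixels positive —
isolated specks far below the 25 px minimum object size — while the
fiber interior, whose excess over the local mean is ≈ 0.6 of the fiber
amplitude (≈ 0.3 intensity units), clears the threshold with a wide
margin.

**Artifact removal.** Interactive editing of non-nervous structures is
replaced by three deterministic filters: minimum component area
(default 25 px), a blob-circularity cutoff (4πA/P², perimeter counted as
boundary edges; elongated fibers score ≈ 0.0–0.2, digital disks ≈ 0.5;
preset cutoff 0.45), and an optional expert-drawn exclusion mask. The
result is always a subset of the input. Circularity is only assessed for
components ≥ 20 px, where the digital perimeter is meaningful.

**Hole filling.** Where the network is locally dense, the threshold
window straddles mostly-foreground regions and punches small holes into
solid profiles; thinning a holed mask produces spurious loops that
inflate both length and branch-point counts. Enclosed background
components of at most `fillHolesPx` (default 50 px, about twice a fiber
cross-section) are therefore filled; genuine network meshes are orders of
magnitude larger and stay open.

**Thinning.** Zhang–Suen parallel thinning runs to convergence, followed
by a sequential cleanup that deletes any non-endpoint pixel whose Yokoi
connectivity number (the count of 8-connected foreground components in
its 8-neighborhood) equals 1 — a provably topology-preserving deletion.
The cleanup matters: parallel thinning alone leaves two-pixel
shoulder/staircase residues on curved tubes, which double-count
adjacency-weighted length and generate junction pixels along plain
curves. The combination yields unit-width, 8-connected skeletons, is
idempotent on thin input, preserves the number of components, and is
deterministic (fixed raster order).

**Spur pruning.** Boundary roughness under noise grows short terminal
twigs whose junctions are not anatomical branch points. Spurs of up to
`spurPrunePx` (default 5 px, below the fiber half-width-plus-noise scale)
are traced from each endpoint and removed, including the base pixel when
its remaining neighbors form a single connected anchor; free-standing
short segments and longer branches are untouched.

**Branch points.** A skeleton pixel with ≥ 3 skeleton neighbors is a
junction pixel; 8-adjacent junction pixels are merged into one branching
point (a single anatomical bifurcation can produce 2–3 junction pixels),
represented by the cluster pixel nearest the cluster centroid. Non-thin
input triggers a warning, not an error.

**Length.** Each unique pair of adjacent skeleton pixels contributes
1 px (orthogonal) or √2 px (diagonal). This estimator is exact on
axis-aligned and diagonal lines and overestimates arbitrary orientations
by ≤ ~8 % (≈ 3 % observed on random-walk fibers). A plain pixel-count
estimator is available (`lengthEstimator = "pixel-count"`) for
sensitivity analysis. Isolated pixels contribute zero.

**Thickness.** Mean thickness is foreground area (µm²) divided by
skeleton length (µm), so thickness × length = area holds exactly for
every image. A zero-length skeleton makes thickness undefined: it is
reported as `NA` with a flag and excluded (not zero-counted) from group
statistics.

**Statistics.** SEM uses the n−1 sample s.d. The t statistic is
(x̄₁−x̄₂)/√(sem₁²+sem₂²) in both raw-value and summary-stat modes, so the
two modes agree to machine precision; the Student variant uses pooled
df = n₁+n₂−2 (identical to the classic pooled-variance test at equal n,
which the tests verify against `stats::t.test`), Welch–Satterthwaite df
is available. Two-tailed throughout — the conservative standard when the
original test's sidedness is not stated. Zero-variance degeneracies
follow the conventions p = 1 (equal means) and p = 0 with a warning
(unequal means). The unit of replication is whatever table the caller
provides (images or samples); `n` is always recorded. No multiple-testing
correction is applied; a note is emitted beyond four comparisons.

# The synthetic-image generator

`generateNetwork` grows fibers as piecewise-linear random walks in
physical (µm) coordinates — the same seed yields the same physical
network at any pixel size. Primary fibers start at uniform positions and
directions; the heading turns by N(0, `curvatureSd`) per 3 µm step;
children spawn at the growing tip with probability `branchProb` per µm,
at ±(45°–90°) from the parent, with width 0.85× a fresh draw from the
width distribution (relative to the cohort mean, so deep branching does
not drive widths to zero). Fibers bounce off the field border and
terminate when they would come closer than 2.5 µm (surface-to-surface) to
another fiber. With a coverage target set, growth stops when the
accumulated centerline-length × width budget reaches the target area;
if the branching process dies out first, additional primaries are seeded.

Three choices trade realism for a recoverable ground truth, and are the
reason the generator can serve as a benchmark at all:

* **No crossings.** Fibers avoid rather than cross each other. In a real
  2-D projection fibers do cross, and every crossing adds a skeleton
  junction that no annotation would call a branch point. Avoidance makes
  "junction clusters ≈ true attachments" an identity the tests can check.
* **Minimum kept length 12 µm.** A fiber blocked after less than ~2 fiber
  widths is discarded entirely (strokes, area, branch count): such stubs
  are below morphological detectability and would otherwise make the
  ground-truth branch count unrecoverable by any detector.
* **End attachments are continuations.** A child attached within 9 µm of
  where its parent terminates forms an elbow, not a Y; it is grown and
  rendered but not counted as a branch point.

Ground truth is computed from the geometry before any degradation:
centerline polylines, exact summed length, attachment count, area-weighted
mean width, and the foreground area of a 4× supersampled rasterization
(the analytic area of overlapping round-capped strokes is intractable;
supersampling bounds the error well below the test tolerances). Rendering
then applies, in order: coverage-weighted attenuation of a 0.82
background (`stainContrast`), non-nervous dark blob artifacts (4.5–6.5 µm
radius disks placed clear of fibers), a smooth multiplicative
second-order polynomial shading field (`shadingAmplitude`), additive
Gaussian noise (`noiseSd`), and clipping to [0, 1]. Because ground truth
derives from draws made before the degradation draws, it is identical
whether or not the image is rendered (`render = FALSE` is the fast path
for calibration studies).

What the generator does **not** emulate: color (RGB) stain separation,
out-of-focus blur, texture of connective tissue, fiber crossings and
anastomoses, vessels/adipocytes with realistic shapes, or 3-D stacks.
Passing the recovery tests therefore shows the chain is correct and
well-calibrated for resolvable filament networks — not that it is robust
to every real-world artifact; the exclusion mask exists precisely for
structures the automated filters cannot judge.

## Presets and the pixel-size decision

The `tlf` preset targets 9.01 % coverage with 5.8 µm fibers and a high
branching rate; `gluteal` targets 2.78 % with 4.9 µm fibers; `th` targets
0.08 %. Both main presets use noise s.d. 0.05 and shading amplitude 0.2,
six blob artifacts, and 512 × 512 px fields at **1 µm/px**. The pixel
size is a deliberate choice: the classic 15 × 15 local-mean window and a
top-hat element of ~2× fiber width are mutually consistent only when a
fiber spans about 4–8 px. At 1 µm/px a 5.8 µm fiber is ~6 px wide, the
window sees fiber and background simultaneously, and a 0.26 mm² field
carries 20–90 true branch points per image. (At, say, 0.25 µm/px the same
window would sit entirely inside one fiber and the threshold would hollow
it.) All physically meaningful outputs are in %, /mm², mm and µm, and the
scale-invariance tests confirm that halving the pixel size at fixed
physical geometry leaves the ground truth unchanged.

# Validation design and problem sizes

The test suite asserts, among others:

* exact oracle equivalence of branch-point counting and length
  measurement against brute-force enumerations on 10⁵ random ≤ 8 × 8
  masks (≤ 12 foreground pixels);
* the thickness identity (thickness × length = area, to 1e-9 relative)
  on every processed image including degenerate ones;
* pixelwise F1 ≥ 0.8 of the final mask against true foreground on both
  presets (256 px fields, noise 0.05, shading 0.2);
* ground-truth recovery on 20 images per preset at full 512 px size:
  area and length within 15 %, thickness and branch counts within 20 %
  (group-aggregate relative error), with every image carrying ≥ 10 true
  branch points, and all four parameters separating the presets at
  p < 0.01;
* a type-I error rate for the area comparison within [0, 0.12] over 100
  null cohorts (n = 6 vs 6, 192 px fields, ground-truth areas);
* byte-identical CSV/JSON outputs across repeated seeded runs.

Field sizes in the tests (192–512 px) are chosen so each property is
measured at the smallest size where it is meaningful: calibration studies
need many replicates but only the ground truth, while recovery needs the
full-size rendered images.

# Known limitations

* The adjacency-weighted length estimator carries a small positive bias
  on oblique fibers; at the preset scale it roughly cancels the end
  erosion of thinning, but both effects are resolution-dependent.
* Thickness is systematically a few percent below the true width because
  thresholding erodes anti-aliased fiber edges while the skeleton length
  is slightly inflated; the bias is shared by both groups in a
  comparison.
* Junction clusters closer than one merge radius (8-adjacency) collapse
  into one branching point; extremely twiggy networks will undercount.
* The statistics module deliberately fits no hierarchy
  (image-within-sample); feed it per-sample means if samples, not
  images, are the unit of replication.
* `EBImage::bwlabel` is 4-connected, so all 8-connected labeling in this
  package goes through its own igraph-based implementation; the two must
  not be mixed when extending the code.
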