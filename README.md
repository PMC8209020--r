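# nervemorph

Quantitative morphometry of immunostained nerve-fiber networks in 2-D
grayscale micrographs.

Peripheral-nerve stains such as S100 (Schwann cells), PGP 9.5 (pan-neuronal)
or tyrosine hydroxylase (sympathetic fibers), developed with DAB, show nerve
fibers as a dark branching network of 3–8 µm filaments on a bright, unevenly
illuminated tissue background. Comparing the innervation of two tissues
requires turning such images into numbers reproducibly. `nervemorph`
implements the standard measurement chain:

1. **Normalize and orient** — intensities to [0, 1], stain signal made
   bright (`normalizeAndOrient`).
2. **Flatten illumination** — a morphological opening with a large disk
   estimates and removes shading and diffuse background
   (`flattenIllumination`).
3. **Top-hat enhancement** — white top-hat with a disk radius ~2× the fiber
   width isolates thin bright structures (`tophatEnhance`).
4. **Adaptive local-mean threshold** — a pixel is nerve iff its intensity
   exceeds the mean of its 15 × 15 neighborhood plus an offset constant
   (`adaptiveThreshold`).
5. **Artifact removal** — deterministic replacement for interactive
   editing: minimum object size, blob-circularity cutoff
   (4πA/P²), optional expert exclusion mask (`removeArtifacts`), plus
   small-hole filling (`fillHoles`).
6. **Skeletonization** — Zhang–Suen thinning with a topology-preserving
   sequential cleanup to a unit-width, 8-connected centerline
   (`skeletonize`), short-spur pruning (`pruneSpurs`), and branch-point
   identification as merged clusters of skeleton pixels with ≥ 3 neighbors
   (`findBranchPoints`).
7. **Morphometry** — the four standard parameters per image
   (`summarizeMorphometry`):
   * positive area fraction (%),
   * branching-point density (/mm²),
   * total network length (mm), from the adjacency-weighted skeleton
     length (orthogonal steps count 1 px, diagonal √2),
   * mean fiber thickness (µm) = foreground area / skeleton length.
8. **Statistics** — group mean ± SEM (`groupSummary`), two-tailed
   two-sample t-tests from raw values *or* from published summaries
   (`tTestGroups`), dense/sparse marker ratios (`markerRatio`), and a
   per-parameter group comparison table (`compareGroups`).

Because benchmark micrographs with known ground truth do not exist, the
package also ships a **synthetic micrograph generator**
(`generateNetwork`, `generateCohort`, `presetSpec`): seeded branching
fiber networks grown in physical coordinates with exact ground truth
(centerlines, total length, branch count, width, supersampled foreground
area), rendered as DAB-like images with multiplicative shading, Gaussian
noise and non-nervous blob artifacts. Presets emulate a densely innervated
aponeurotic fascia (~9 % positive area) and a sparse epimysial fascia
(~2.8 %). The whole pipeline is validated end-to-end against this ground
truth in the test suite.

## Worked example

```r
library(nervemorph)

co <- generateCohort(presetSpec("tlf"), presetSpec("gluteal"), 3, seed = 7,
                     groupNames = c("tlf", "gluteal"))
res <- runPipeline(lapply(co, `[[`, "image"), presetConfig(),
                   vapply(co, `[[`, character(1), "group"))
res$perImage[, 2:6]
#>     group positive_area_pct bp_density_per_mm2 total_length_mm mean_thickness_um
#> 1     tlf             8.378             213.62           4.444             4.942
#> 2     tlf             8.540             232.70           4.568             4.901
#> 3     tlf             8.301             221.25           4.568             4.763
#> 4 gluteal             2.755              68.66           1.763             4.097
#> 5 gluteal             2.667              68.66           1.563             4.472
#> 6 gluteal             2.817              80.11           1.703             4.336

res$groupStats[, c("parameter", "mean_a", "sem_a", "mean_b", "sem_b", "t", "df", "p")]
#>            parameter  mean_a   sem_a mean_b   sem_b      t df         p
#> 1  positive_area_pct   8.406 0.07049  2.746 0.04362 68.281  4 2.756e-07
#> 2 bp_density_per_mm2 222.524 5.54263 72.479 3.81470 22.300  4 2.394e-05
#> 3    total_length_mm   4.527 0.04145  1.676 0.05914 39.466  4 2.463e-06
#> 4  mean_thickness_um   4.869 0.05401  4.302 0.10953  4.641  4 9.729e-03
```

Each per-image row holds the four morphometric parameters of one 512 × 512
µm field; the group table shows that the dense ("tlf") preset exceeds the
sparse ("gluteal") one in every parameter, with two-tailed Student t-tests.
Significance calls can also be reproduced from published summaries alone:

```r
tTestGroups(new("GroupStats", n = 6L, mean = 500.9, sem = 43.1),
            new("GroupStats", n = 6L, mean = 140.3, sem = 31.6))
#> TTestResult (student, summary-stats): t = 6.747, df = 10, p = 5.059e-05
```

## Command line

A thin CLI over the same functions is installed at `exec/nervemorph`:

```sh
nervemorph simulate --out sim/ --seed 7 --n-per-group 10
nervemorph analyze  --manifest sim/manifest.csv --out results/
nervemorph compare  --per-image results/per_image.csv --out results/
```

`simulate` writes single-channel TIFFs with JSON ground-truth sidecars and
a CSV manifest; `analyze` writes `per_image.csv`, `group_stats.csv` and a
`report.json` embedding the configuration hash, so every number is
traceable to the exact parameter set.

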