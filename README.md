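# riceHRY

Head rice yield (HRY) — the fraction of milled rice kernels that are at
least three-fourths of the intact kernel length (GB/T 21719-2008) — is a
key rice quality attribute, traditionally measured by slow, subjective
manual screening. `riceHRY` measures it from top-down images of bulk
milled rice on a dark conveyor background, for grain-quality labs and
phenotyping pipelines that want a reproducible, fully scripted
measurement.

The pipeline:

1. **Preprocessing** — Otsu thresholding of the bright kernels against the
   dark belt, removal of reflection specks by component area, one pass of
   3×3 median edge smoothing.
2. **Touching-kernel separation** — for each connected component, the
   *edge center mode proportion* `k(t) = PF / SM` (foreground pixels `PF`
   inside a square template of size `SM` centred on boundary pixel `t`) is
   sampled clockwise along the boundary. Concave points — the crevice
   corners where two kernels touch — are peaks of runs with
   `k(t) ≥ λ`, where `λ = E(k) + a·σ(k)` with a per-variety coefficient
   (`a ≈ 3` japonica, `a ≈ 2` indica). Concave points are paired under a
   collaborative wedge constraint built from each point's template
   crossover points, and matched pairs are cut with a 1-px line.
3. **Length and classification** — each kernel's length is the longer side
   of its minimum enclosing rectangle (rotation search, 3° default step;
   maximum-distance and centroid-rotation comparators included), and the
   kernel is head rice iff `length ≥ 0.75 × reference length`, the
   reference being the mean measured length of ten intact kernels.
4. **HRY** — `HRY = S_hr / S_total`, the head-kernel pixel area over the
   total kernel pixel area (area standing in for mass at constant kernel
   thickness and density).

A ground-truthed synthetic scene generator (`makeScene()`) emulates the
acquisition: superellipse kernels in japonica-like and indica-like
geometry regimes, touching chains of 2–5 kernels with 1–4 px contact
overlap, a controllable broken-kernel fraction, belt noise and specks.
Every stage of the pipeline is validated against its ground truth.

## Worked example

```r
library(riceHRY)

scene <- makeScene(60, brokenFraction = 0.2, variety = "japonica", seed = 42)
scene
#> GrainScene: 1582 x 1899 px, 60 grains ( japonica profile )
#>   broken: 12  head-area fraction: 0.8702  seed: 42

ref <- calibrateReference("japonica", seed = 7)   # mean MER length, 10 intact kernels
cfg <- hryConfig(scaleMmPerPx = 1, referenceLengthMm = ref,
                 variety = "japonica")
res <- runScene(scene, cfg)
res
#> HeadRiceResult: 59 grains, HRY = 0.8716 (S_hr = 102644 / S_total = 117763 px)

truthHeadArea(scene) / truthTotalArea(scene)
#> [1] 0.8702366
```

59 of the 60 kernels are recovered individually (one neck stays uncut —
typical single-scene separation accuracy is 95–100%), and the measured
HRY (0.8716) tracks the ground-truth head-area fraction (0.8702) to a few
tenths of a percent. `perGrain(res)` holds the per-kernel table (label,
area, length in px/mm, head/broken call); `runImage()` runs the same
pipeline on a PNG/TIFF file and writes the table as CSV plus a JSON
summary. A thin CLI over these functions is installed at
`inst/scripts/hry` (`synth`, `measure`, `benchmark` subcommands).

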