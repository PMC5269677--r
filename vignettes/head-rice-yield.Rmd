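---
title: "Measuring head rice yield by concave-point separation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring head rice yield by concave-point separation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riceHRY)
```

## The measurement problem

Head rice is milled rice whose kernel length is at least three-fourths of
the intact kernel length (Chinese national standard GB/T 21719-2008), and
head rice yield (HRY) — the mass fraction of head rice — is a primary
quality and pricing attribute. Manual screening is slow and subjective.
When bulk kernels are imaged top-down on a dark conveyor, mass can be
replaced by projected pixel area: kernels of one variety have nearly
constant thickness and density, so mass is proportional to area and

$$\mathrm{HRY} = \frac{S_{hr}}{S_{total}},$$

the ratio of summed head-kernel pixel area to summed kernel area. The
obstacle is that kernels in bulk touch each other; a connected blob of
several kernels must be split into individual kernels before any length
can be measured. This package implements that pipeline: threshold,
despeckle and smooth the image; separate touching kernels by concave-point
detection and constrained matching; measure each kernel's length with a
minimum-enclosing-rectangle (MER) search; apply the 3/4 rule; report the
area-ratio HRY.

## Concavity scoring: the edge center mode proportion

For a boundary pixel $t$ of a connected component, the **edge center mode
proportion** (ECMP) is

$$k(t) = \frac{PF}{SM},$$

the number of foreground pixels $PF$ inside a square template centred on
the pixel, over the template size $SM = T^2$. On a straight edge the
template is split roughly in half ($k \approx 0.56$ for $T = 9$, the extra
fraction coming from the centre row itself being foreground); at a convex
corner the foreground quadrant covers about $25/81 \approx 0.31$; at a
reflex (concave) corner it covers about $65/81 \approx 0.80$. Concave
points — the two crevice corners that form wherever two convex kernels
touch — therefore appear as *peaks* of the ECMP profile sampled clockwise
around the component boundary.

One sentence in the source description of this score has the polarity
reversed ("lower ECMP indicating a more concave edge"). The geometry above
and the peak-picking detection with a threshold of ~0.72 both require the
opposite reading, which is what this package implements: concave points
score **high**.

Choices fixed here:

* **Template size** scales with the image at 300:1 — a 3000×2500 px frame
  uses a 9×9 template (`templateSizeForImage()`), clamped at 3×3 and
  rounded down to odd.
* **Boundary trace**: Moore neighbour tracing, clockwise in screen
  orientation, seeded at the lexicographically smallest (row, then column)
  edge pixel, terminated when the trace re-enters the start and repeats
  its second pixel. Interior holes are ignored.
* **Border handling**: templates overhanging the image are padded with
  background. This biases frame-edge kernels toward "convex", which
  avoids false cuts — the conservative failure.

## The adaptive threshold λ

The detection threshold is reconstructed as

$$\lambda = E(k) + a \cdot \sigma(k),$$

with $E(k)$ and $\sigma(k)$ the mean and sample standard deviation of the
profile over its $N$ boundary samples and $a$ a per-variety coefficient:
roughly 3 for the shorter, rounder japonica kernels and 2 for the longer
indica kernels (longer varieties get the smaller coefficient). This form
uses exactly the quantities the source equation names, and on a typical
cluster profile ($E \approx 0.48$, $\sigma \approx 0.08$, $a = 3$)
reproduces the printed threshold magnitude $\lambda = 0.72$.

Positions with $k(t) \ge \lambda$ are grouped into maximal circular runs;
each run contributes one concave point, the peak of $k$ within the run
(ties to the earliest position).

Two robustness rules, both documented degenerate-case handling rather than
tuning knobs:

* A constant profile gives $\lambda = E(k)$ and detects nothing.
* The run threshold is floored at **0.65**. A nearly constant profile — a
  uniform-width kernel whose 45° staircase edges ripple between about 0.52
  and 0.63 — collapses $\sigma$, and a purely adaptive $\lambda$ would sit
  inside the ripple and hallucinate concave points. The floor sits just
  above the straight-edge score plus ripple and far below any genuine
  crevice corner (≥ ~0.8), so it cannot suppress a real neck.

## Collaborative constraint matching

Each pairwise contact yields two concave points, one on each side of the
neck; a chain of $n$ kernels yields $2(n-1)$. Matching the right pairs is
the crux once three or more kernels touch. For a basic point $A$, the
boundary is walked both ways until it exits the ECMP template window; the
last pixels inside are the crossover points $M$ and $N$. The admissible
region for $A$'s matching partner is the closed wedge with apex $A$
bounded by the rays *opposite* $AM$ and $AN$ — the continuations of the
lines $MA$ and $NA$ through the apex, which point across the neck into the
kernel mass. Among unmatched concave points of the same component inside
the wedge, the nearest (Euclidean) is taken; each point matches at most
once; a point with no admissible partner stays unmatched and simply
produces no cut. Basic points are visited in boundary order, which makes
the "random" starting point of the original description deterministic and
reproducible.

If $M$, $A$, $N$ are collinear the wedge degenerates; the admissible
region falls back to the open half-plane on the local-foreground side,
using the foreground centre of mass of the template window.

Matched pairs are cut with a 1-px line. The line is Bresenham thickened to
a 4-connected path: a plain 8-connected line does **not** disconnect an
8-connected component (components leak through the diagonal steps), which
is easy to miss and silently voids the separation. Post-cut fragments
smaller than 25% of the smallest plausible kernel area *and* adjacent to a
cut line are merged back into their largest neighbour; genuine small
kernels are never near a cut and are left alone.

## Kernel length and the head/broken call

Three length estimators are provided; MER is the primary one.

* **`merLength()`** rotates the contour about its centroid over a grid of
  angles covering 90° (default step 3°), takes the axis-aligned bounding
  box at each angle, and keeps the box of minimum area; the longer side is
  the kernel length. An exact rotating-calipers mode over the convex hull
  (`method = "exact"`) serves as the oracle in the test suite; the 3° grid
  stays within a cosine factor plus one pixel of it.
* **`medLength()`** is the maximum pairwise distance between contour
  points (computed on the convex hull, identical to the brute-force scan).
  It measures the diagonal, which *over*-estimates the length actually
  standardized — the reason it misclassifies borderline kernels even
  though its omission rate is trivially zero.
* **`crLength()`** rotates the contour about its centroid and records the
  maximum horizontal extent. The source never defines this "central
  rotatable" comparator precisely; it is implemented over a 180° sweep so
  that the major axis always passes near horizontal, which makes the
  dominance property (CR ≥ MER − 1 px) hold for every orientation. It is a
  comparator, not a primary result.

Pixel-extent convention: lengths of rasterized contours are
$\max - \min + 1$, so a horizontally placed rectangle spanning 30 columns
measures exactly 30 px. One consequence: on near-circular blobs MER (with
its +1) can exceed MED by up to one pixel, so the "diagonal dominates"
inequality between MED and MER is only asserted to 1 px on blunt shapes.

`classifyHead()` applies the 3/4 rule **boundary-inclusive**: a kernel at
exactly three-fourths of the reference length counts as head rice. The
reference length is the mean measured length of ten intact kernels
(`referenceLength()`, `calibrateReference()`). Measuring the reference
with the *same* MER pipeline as the kernels under test matters: the ~1 px
rasterization-plus-smoothing bias then cancels at the 3/4 boundary instead
of systematically shifting borderline calls.

A ten-kernel reference also carries ~2% sampling noise from which kernels
were drawn. The standard's reference is *defined by* the selected kernels,
so when benchmarks score head/broken calls, the ground-truth label shares
that reference — truth compares a kernel's true length against the
calibration kernels' true mean, while the classifier compares measured
length against their measured mean. The omission and false-detection
rates then quantify what they should: the length *measurement* error,
with both the systematic bias and the kernel-selection noise cancelled.
(`calibrateReference(details = TRUE)` exposes both reference values.)

## The synthetic scene generator

No real image sets are distributed with the method, so validation runs on
a ground-truthed generator (`makeScene()`) that emulates the acquisition
conditions:

* **Working scale** 12 px/mm — a 3000 px frame over a 250 mm belt — with
  100–200 kernels per 2500×3000 frame; auto-sized canvases keep that
  density, while benchmarks fix the canvas to sweep density.
* **Kernels** are superellipses with exponent 2.5 (blunter-ended than an
  ellipse, matching milled kernel silhouettes): japonica-like 64–80 px
  long with aspect ratio 1.8–2.2, indica-like 84–104 px with 2.8–3.4.
  Broken kernels are truncated by a single chord to a fraction of their
  full length; a kernel is "broken" exactly when that fraction is below
  0.75.
* **Clusters** of 2–5 kernels are built as chains: each kernel slides
  toward its predecessor along a random direction (turns limited to ±60°)
  until the masks overlap, with 1–4 px contact depth. Two constructive
  constraints realize the design rule that every pairwise contact carries
  two sharp concave points: the two outlines must cross at ≥ 25° at both
  neck endpoints (no tangential grazes), and after the 3×3 smoothing each
  neck endpoint of the two-kernel union must still score ≥ 0.80 — the
  right-angle reflex landmark — in a 9×9 window. Contacts also keep at
  least 3 shared pixels so a graze cannot be erased by smoothing, and at
  most ~150 so there is no heavy occlusion. Rejected geometries are simply
  re-drawn.
* **Rendering**: belt ≈ 10/255 with Gaussian noise σ = 3, kernels
  ≈ 200/255, bright specks of 1–13 px at ≈ 180/255. Edges are hard;
  defocus, shadows and motion blur are not modelled.
* **Determinism**: a scene is a pure function of its arguments including
  the seed; the caller's RNG state is restored.

What passing tests on these scenes do and do not show: they validate the
separation logic, the length measurement and the HRY accounting under
controlled contact geometry and clean contrast. They do not certify
performance on real belt images with soft edges, specular highlights,
occlusion from heaped kernels, or fracture faces that are rough rather
than straight chords.

Known generator-related limits, found while validating and left as
documented behaviour:

* Near-tangential and deeply shallow contacts (excluded by construction
  here) produce one-sided crevices that the ECMP threshold can miss; on
  real images these are exactly the contacts that account for separation
  accuracy below 100%.
* Clusters consisting *only* of severely truncated kernels inflate
  $\sigma(k)$ through their cut-face corners, which can push $\lambda$
  above the neck peaks. The all-broken degenerate check therefore uses
  non-touching kernels; it verifies classification, not separation.
* The ground-truth neck endpoints are computed from the raw overlap lens;
  smoothing relocates the actual crevice corner by a pixel or two, so
  localization is asserted to 5 px rather than the 2 px the raw geometry
  would suggest.

## Benchmarks and problem sizes

`runBenchmark()` generates seeded scenes, runs the full pipeline, and
tabulates per-scene separation accuracy (detected / true kernel count, the
headline metric), HRY error against generator truth, and head-call
omission and false-detection rates obtained by matching each detected
kernel to the ground-truth kernel of maximal pixel overlap. The package's
acceptance script (`scripts/acceptance.R`) evaluates four quantities on
fixed problem sizes chosen to keep a full run in a few CPU-minutes: six
150-kernel touching-grain scenes (three per variety profile) for
separation accuracy and HRY relative error; 500 singleton kernels with
length fractions drawn uniformly on [0.55, 1] for the boundary-straddling
head-call error rates; and a 100/150/200 kernels-per-frame density sweep
on a fixed 2500×3000 canvas for HRY deviation under crowding. With
controlled cluster-size weights the density sweep holds contact structure
fixed, so the accuracy-versus-density trend is much weaker here than on
real belts, where crowding itself creates more touching; the benchmark
asserts non-degradation with a small slack rather than a strict decrease.

## Worked example

```{r example}
scene <- makeScene(60, brokenFraction = 0.2, variety = "japonica", seed = 42)
scene

ref <- calibrateReference("japonica", seed = 7)
cfg <- hryConfig(scaleMmPerPx = 1, referenceLengthMm = ref,
                 variety = "japonica")
res <- runScene(scene, cfg)
res

c(truth = truthHeadArea(scene) / truthTotalArea(scene), measured = hry(res))
```

The per-kernel table (`perGrain(res)`) carries label, pixel area, length
in px and mm, the measuring method and the head/broken call, and is what
`runImage()` writes as CSV next to the JSON summary.
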