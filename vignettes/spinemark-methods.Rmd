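---
title: "Lumbar spine annotation: models, parameters, and design choices"
author: "spinemark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lumbar spine annotation: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinemark)
```

This vignette is the package's account of its science: what each stage
computes, which parameters matter and why their defaults are what they are,
what the synthetic phantom does and does not emulate, and where the design
was genuinely open.

## The problem

Pfirrmann grading quantifies lumbar intervertebral disc (IVD) degeneration
on a 1–5 ordinal scale from T2 signal, nucleus–annulus distinction, and disc
height. Given a mid-sagittal T2 slice and a six-region segmentation (from
any backend — the segmentation network itself is out of scope here), the
package answers three questions per disc: *which disc is it* (L5/S1 up to
L1/L2), *how tall is it* in millimetres, and *what grade is it*.

## Geometry normalization

All analysis runs on a 384×384 working grid. A study with pixel spacing
`ps` mm/px and (square) dimension `dm` px is resampled with cubic
interpolation (nearest-neighbour for labels, which can never invent codes),
and the spacing becomes `ps' = ps · dm / 384`, preserving the physical field
of view (`dm · ps = 384 · ps'`). Intensity images are 8-bit; DICOM stored
values are windowed to [0, 255] by linear min–max scaling, the simplest
reproducible choice since acquisition windowing varies by scanner and is not
recoverable from the pixel data alone. Non-square images or anisotropic
spacing are rejected rather than silently resampled: the single-spacing
bookkeeping would be wrong for them, and sagittal lumbar protocols
essentially always produce square slices.

## Label maps and post-processing

The six regions are coded Anterior = 1, PosteriorA = 2, PosteriorB = 3,
Vertebrae = 4, IVD = 5, Sacrum = 6. Foreground regions use 8-connectivity
and holes are 4-connected enclosed background — the standard dual pairing
that avoids topological paradoxes (a diagonal crack would otherwise be both
inside and outside). Validation checks the six labeling requirements;
violations are returned as data, not errors, because an automatic
segmentation is expected to violate them and post-processing exists to
repair it.

Post-processing follows five steps: keep the largest CCR of Anterior,
PosteriorA and Sacrum (merging smaller ones into their surroundings) and
close its holes; close holes of every PosteriorB CCR; keep the largest
Vert–IVD union component, reassign detached disc/vertebra fragments, and
fill union holes; finally merge any disc/vertebra CCR under 20 px (strictly:
a 20-px component survives). "Merge with the surrounding region" is made
concrete as the mode of the codes on the component's external 8-neighbour
ring, ties to the smallest code — a deterministic rule that reduces to the
obvious answer when a fragment is embedded in one region. Union holes whose
vertical neighbours are vertebra above and below are filled as IVD (they sit
where a disc should be); other holes take the mode of their ring. The whole
procedure is idempotent, which the test suite checks on 200 seeded phantoms
with injected fragments and pinholes.

Segmentation quality uses per-region accuracy (recall), IoU, and boundary
F1 (BFScore); the mean score averages the six Vertebrae/IVD numbers. The
BFScore distance tolerance is not standardized anywhere; the package uses
0.75% of the image diagonal, rounded up (5 px at 384×384), a common default
in segmentation toolboxes, and exposes it as a parameter.

## Spine line and naming

The Sacrum+Vertebrae+IVD union is reduced to a unit-width skeleton by
Zhang–Suen thinning (any homotopy-preserving 8-connected thinning would do).
Thinning produces the two true endpoints plus possible branch endpoints
where the region bulges laterally. The lowest endpoint (largest row; ties to
largest column) starts the traversal — it is guaranteed to lie in the
Sacrum for any anatomically plausible map — and A\* with unit/√2 move costs
and the Euclidean heuristic orders the pixels to the topmost endpoint.
On a unit-width skeleton the optimal path is essentially the unique simple
path, so the choice of pathfinding algorithm is immaterial; branch pixels
off the path are discarded.

Walking the path bottom-up, each maximal run of IVD-coded points maps to the
disc CCR containing it and receives the next name (L5/S1 first); vertebra
runs likewise (L5 first). Runs interrupted by at most two other-coded points
are bridged — single-pixel label noise on the line must not split a disc in
two — with one crucial exception: a vertebra run is never bridged across
IVD-coded points, because a collapsed grade-5 disc legitimately crosses the
path in as little as two points and bridging it would fuse two vertebrae.
The asymmetry is anatomical: discs can be 2 px thin, vertebrae cannot.
More than five disc runs, or none, is an anatomy error. A named CCR touching
the image border is flagged `truncated` (the field of view often cuts the
topmost vertebra).

## Height measurement

Measurement runs in a ×4 cubic-upscaled frame after Gaussian smoothing
(σ = 0.5 px at original scale; the paper-scale images are mildly noisy and
heavier smoothing starts displacing the very edges being measured). Top
boundary points are disc pixels 8-adjacent to the superior vertebra; bottom
points adjoin the inferior structure (Sacrum for L5/S1). Each boundary's
middle 30% (by column order) gives a centre point and a best-fit line;
orthogonal (total least squares) regression is used because it stays stable
if an endplate is steep, and coincides with ordinary regression for the
near-horizontal endplates that dominate.

The perpendiculars to the two fits, oriented into the disc (sign fixed by
the dot product with the direction to the disc centroid), are intersected
with the opposite fit lines; `M_T` and `M_B` are the midpoints of
`(C_T, C'_B)` and `(C_B, C'_T)`. One step of the published construction
refers to the bottom fit line twice; the package adopts the symmetric
reading (the second ray intersects the *top* fit line), which is the only
reading consistent with the construction's illustration and with the
midpoint formulas that follow.

Refinement searches the segment from `M − u` to `M + k·u` (`u` the unit
bisecting direction, `k = 8` upscaled px ≈ 1.5 mm at 0.7292 mm/px) for the
pixel with the largest aligned Prewitt response `b_p = cos(β_p − α)·m_p`.
Three numerical guards matter in degenerate inputs:

* **Noise floor.** If no pixel scores above the Prewitt response to a
  one-grey-level step (3), there is no edge aligned with the search
  direction and `M` is kept. Without this, sub-quantization interpolation
  ripple in a flat dark disc would drag the endpoint up to `k` pixels.
* **Plateau ties.** Scores within 2% of the maximum straddle the same
  smoothed edge; they are treated as tied and resolved toward `M`. This
  removes a ±1 px coin-flip between the two pixels either side of an edge,
  which otherwise dominates the measurement variance.
* **Crossing cap.** The search range is capped at half the initial segment
  length, so the two endpoint searches can never cross: in a sub-3 mm disc
  the opposite endplate lies inside the default search range and its edge is
  aligned with the search direction.

Height is `‖M'_T − M'_B‖ · ps' / 4` mm. On noise-free phantoms at the
default geometry (curvature, per-disc tilt up to 5°) recovered heights sit
within ±0.25 mm of construction; the acceptance suite asserts ±0.5 mm,
monotonicity in constructed height, and <5% change under rotations up to
10°.

## Nucleus features

Because radiologists judge nucleus brightness *relative to vertebrae*, each
image is first offset by `gl_vert − gl_vert_mean`, where `gl_vert` is the
image's mean vertebra intensity and `gl_vert_mean = 69` is the dataset
reference (re-estimable with `estimate_reference_mean()`). A global exposure
offset cancels exactly unless it saturates the 8-bit range; the tests assert
feature equality under ±30 offsets.

The nucleus is found inside each disc by eroding the disc mask to 80% of its
area (erosion has no native percentage parameter, so 3×3 erosions iterate
until the area target is met), then descending a threshold from the region
maximum in steps of 5 — one quantization bin — until the candidate set
covers ≥30% of the shrunk region *and* its largest connected component,
after closing with a radius-4 disc (≈1 original pixel), covers ≥20%. The
accepted component eroded to 90% is the inner nucleus. If the threshold
reaches the region minimum first, the disc has no distinct nucleus (typical
of grade 4–5) and the eroded disc is used with a `fallback` flag.

The feature is a self-similar colour correlogram: intensities capped at
`gl_max = 150` and quantized into `n_gl = 30` bins of width 5 (the cap value
itself is clamped into the last bin so exactly N = 30 colours exist); for
every ordered pixel pair at chessboard distance exactly `d = 4` (the
upscaling factor — one original pixel), counts `C[i, j]` are row-normalized
into conditional probabilities; the band `|i − j| ≤ w` is emitted row-major,
with length `N(2w+1) − w(w+1)`. Ordered pairs make each row a proper
conditional distribution; the L∞ metric at exact distance follows the
correlogram literature. The band half-width default is `w = 2` (length 144),
the value the feature's illustration uses; the experiment value is unstated,
so it is a config parameter. The implementation is vectorized over the 32
ring offsets and is verified against an O(n²) brute-force pair enumeration
in the tests.

## Grading

A measured height under 3.0 mm (strictly) is grade 5, before any classifier
runs — disc collapse is definitional for grade 5 and needs no texture
evidence. Grade-5 ground truth is accordingly excluded from classifier
training. Remaining discs are classified 1–4 with per-sample weights
`tw_c = median(f)/f_c`, which give the median-frequency class weight 1 and
inflate rare classes. Six families are implemented (ensemble of bagged
trees, single tree, k-NN, SVM, LDA, feed-forward network) behind one
interface with seeded, stratified 10-fold cross-validation; the ensemble is
the default and reference configuration (15 trees, minimum leaf size 1, 20
sampled variables per split). Its published split criterion ("twoing") is
not available in any maintained R tree backend; Gini impurity substitutes,
a documented deviation that affects split ordering only. Probability ties
resolve to the lowest grade.

Evaluation reports a 5×5 confusion matrix, per-grade accuracies, and their
frequency-weighted mean `Σ f_c·acc_c / Σ f_c`, which equals plain accuracy
when `f` is the empirical class counts.

Two protocol modes mirror the intended deployment: training computes
features and heights from ground-truth label maps, prediction recomputes
them from post-processed (automatically segmented) maps; `run_experiment()`
wires both.

## The phantom

The generator renders what the pipeline assumes and the statistics it must
cope with, not anatomy per se:

* **Geometry.** Anatomically proportioned blocks at 0.7292 mm/px: vertebral
  bodies 36 px (~26 mm) tall and 56 px (~41 mm) wide, sacrum 60 px, the
  topmost vertebra extended 20 px (the column continues beyond the lumbar
  field, which also keeps the skeleton's top endpoint inside it). Disc
  heights by grade: 9–12, 8–11, 6.5–9.5, 4.5–7.5 mm for grades 1–4 and
  2.0–2.8 mm for grade 5 (always under the 3 mm rule). A sinusoidal
  horizontal offset (amplitude 6 px) bends the column; each disc's endplates
  tilt together by up to ±5°; optional lateral bumps on vertebrae force
  skeleton branches.
* **Intensities.** Vertebrae 69 (anchoring the brightness reference),
  annulus 35, sacrum 50, background/soft tissue 15–30; nucleus means
  160/130/95/60/45 with s.d. 4/8/14/18/20 for grades 1–5 — brightness falls
  and texture rises with grade, separable but overlapping. A per-study
  exposure offset and additive Gaussian noise (s.d. 3) sit on top,
  clamped to [0, 255].
* **Partial volume.** The image (not the label map) is rendered with exact
  vertical coverage fractions at the endplate curves: a voxel straddling an
  interface carries the area-weighted mixture, as MRI voxels do. Hard-edged
  rendering would instead produce rasterization staircases whose phase
  biases sub-pixel edge localization — an artifact of synthesis, not of
  imaging. The nucleus is a fourth-power superellipse spanning the full disc
  thickness, flattened against the endplates over the central columns, which
  is where the bisecting segment meets it.
* **Ground truth.** Per-disc name, grade, and height `h_px · cos(tilt) · ps`
  (the perpendicular thickness of the rendered slab).

What the phantom does *not* emulate — and what green tests therefore do not
demonstrate about clinical data: true anatomical shape (endplate concavity,
osteophytes), endplate trauma that fuses disc and vertebra signal (the known
failure mode of the height stage on real data), bias fields and coil
inhomogeneity, and inter-rater ambiguity in the ground truth itself.
Classifier accuracies on phantom batches are a recovery check under known
effect sizes, not an estimate of clinical accuracy.

## Problem sizes in the test and acceptance suites

The suites exercise: 200 seeded phantoms for post-processing idempotence
and validity; 50 phantoms (3–5 discs, curvature, tilt, bumps) for the
naming-accuracy check; ten noise-free phantoms (~48 discs) for height
recovery plus dedicated monotonicity and rotation batteries; and a 240-disc
balanced batch (grades 1–4, 10-fold CV, permuted-label baseline) for grade
recovery, with a further 12-study batch asserting the grade-5 rule end to
end. These sizes give stable pass/fail behaviour for each property while
keeping a full run in single-digit minutes on one core.

## Known limitations

* Naming stops at L1/L2; transitional anatomy (sacralization,
  lumbarization) is not detected.
* The height stage measures the central bisecting segment only; no
  anterior-to-posterior height profile or shape descriptors.
* The grade-4/5 boundary inherits the height stage's failure modes: a disc
  whose measured height is wrong in either direction can cross the 3 mm
  rule. On textured phantoms roughly 1% of grade-4 discs collapse below the
  rule, mirroring the behaviour expected on clinical data.
* The DICOM reader handles little-endian uncompressed single-frame files
  and only the attributes the pipeline needs; it is an input convenience,
  not a general DICOM implementation.
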