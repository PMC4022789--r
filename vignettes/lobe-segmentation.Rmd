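---
title: "Fissure detection and five-lobe segmentation: model, parameters and design notes"
author: "lobeseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fissure detection and five-lobe segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains what the pipeline computes, the assumptions it
rests on, the parameters that matter (with units and defaults), what the
synthetic phantom does and does not emulate, and the numerical and
design choices made where the method leaves room.

## The problem and the anatomical model

The five lung lobes are separated by pulmonary fissures: thin
(1–3 mm) double sheets of visceral pleura that show up in CT as faint
bright lines, a little denser than the aerated parenchyma around them
and often incomplete. Direct intensity-based detection is fragile; the
pipeline instead exploits a robust anatomical fact — *the tissue
immediately around a fissure is free of sizeable vessels and bronchi* —
to localize a candidate band first, and only then looks for the ridge
inside it.

All processing happens on a volume in canonical orientation (axis 1
right→left, axis 2 anterior→posterior, axis 3 inferior→superior), so a
sagittal slice fixes the first index, a coronal slice the second, an
axial slice the third. Voxel indices are 1-based; parameters quoted in
"pixels" act in index space, all distances are reported in mm via the
voxel spacing.

## Stage by stage

**Lung segmentation.** Acceptance band [−930, −650] HU (aerated lung
lies near −880 HU; the lower bound keeps outside air and the tracheal
lumen out, the upper bound keeps soft tissue out), 3D connected
components, two largest kept. Closing with a square 7 × 7 kernel is
applied per axial slice — deliberately 2D, so the kernel size has the
same meaning on anisotropic stacks. Dense structures above −300 HU
(vessels, airway walls) are then removed; the vessel-removed mask is
what the fissure scan sees. The left/right split takes the two largest
components by x centroid, with a fallback cut at the minimum-area
sagittal plane over the middle third of the x range when the lungs
touch.

**SAFS.** Per lung, the two sagittal slices at 40% and 60% of the x
extent are scanned (the empirical 0.4/0.6 constants keep the slices away
from the mediastinum and the lateral wall). For each angle θ a family of
parallel Bresenham lines, one per integer perpendicular offset, is
rasterized; per line R counts lung-mask pixels and L is the longest
contiguous run of lung-mask pixels darker than `air_cut`. A line is
accepted iff R > r and L/R > k, with r = 50 px and k = 0.6 (values that
were found optimal in the ranges 30–80 and 0.4–0.7 respectively). The
union of the accepted lines' run segments — not the full lines — forms
the candidate regions at each angle: the run segment is the part of the
line that is actually vessel-free, so the region never contains a vessel
pixel, and the per-line statistics below measure fissure-band coherence
rather than raw lung width. The largest 8-connected component per angle
is scored with

P = w₁·N′ + w₂·σ_R′ + w₃·R̄′

where N is the number of accepted lines meeting the component and
σ_R, R̄ summarize the lengths of their segments inside it. The score
formulation is a plain weighted sum of incommensurate quantities, so the
features are z-standardized across the per-slice candidate set and the
default weights are (1, −1, 1): more lines and longer segments raise P,
spread lowers it. A raw-weight mode (`standardize = FALSE`) applies the
weights to the bare features instead. Ties keep the earliest angle;
equal-area components tie-break on the lexicographically smallest
(row, col) pixel — determinism everywhere.

`air_cut` deserves a note. It separates "empty" (vessel-free) tissue
from vessels and bronchial walls, and is therefore tied to the HU
distribution of the data, not to the method: the clinical default is
−970 HU, which suits scanners whose parenchyma dips that low. On the
package's phantom, whose parenchyma sits at −880 ± 20 HU and whose
fissure sheets at −660 HU, a −970 cut would classify nothing as empty
and SAFS would reject every line; `phantomConfig()` therefore places the
cut just above the fissure HU (−640), between the aerated+fissure tissue
and the vessels — the same role, restated for the phantom's histogram.

**Enhancement and tracing.** Ridges are enhanced per 2D slice with a
multiscale Hessian filter: Gaussian smoothing at scales
{0.7, 1, 1.4, 2} mm (σ divided by the per-axis spacing, so anisotropic
slices are handled physically), σ²-normalized central-difference
Hessian, closed-form eigenvalues ordered |λ₁| ≤ |λ₂|, response
exp(−(λ₁/λ₂)²/2β²)(1 − exp(−(λ₁²+λ₂²)/2c²)) for λ₂ < 0 and zero
otherwise, maximum over scales. β = 0.5 suppresses blobs; c defaults to
half the maximal Hessian Frobenius norm of the slice per scale. A
numerically flat slice (maximal norm below 10⁻⁸) returns an all-zero
response rather than amplifying rounding noise.

The cost image C = max(E) − E feeds a uniform cost search over the
8-connected pixel graph restricted to the candidate region; an edge
costs the value of its destination pixel, diagonal steps are *not*
√2-weighted by default (an optional mode adds the scaling), and the
priority queue breaks ties by insertion order, making the trace fully
deterministic. Start and goal sets are the 2% tails of the region
pixels' projection on the region's principal axis — the band is
traversed lengthwise whatever its orientation. Adding a constant to C
shifts a path's cost by the constant times its hop count, so optima of
different lengths may swap; this is a property of the edge-cost
convention, not a bug, and the tests check the corrected statement.

Each traced line carries its per-pixel enhancement as a `support`
vector. Pixels with support below 20% of the path maximum are traversal
filler — typically where the path runs past the end of an incomplete
fissure or through a ridge-free corner of the band — and are dropped
before the line is used for markers or surface points. Without this
trim, the sagittal horizontal-fissure line keeps walking upward after
the sheet ends and drags the coronal bands with it. A whole line whose
mean support is under 10% of the region maximum is flagged
`lowConfidence`.

For the right lung the oblique fissure is found first; the horizontal
fissure is then searched only in the part of the lung above the detected
oblique line — in the sagittal scan *and* in the coronal bands — since
near the crossing the two sheets otherwise capture each other's traces.

**Surface fit.** The coronal traces form the PFP cloud. Subsampling
keeps points on a sparse (x, y) grid (greedy, ascending (y, x) scan
order; a candidate is rejected when a kept point is closer than the grid
spacing in both x and y) and only where the surrounding 11³ voxel cube
holds more than 80 PFP points — isolated, unreliable points are
discarded. Off-surface points sit d = 10 px along the averaged normal of
all point pairs in the cube (each pair's cross product, sign-aligned to
a per-fissure reference direction, at most 2000 pairs). The reference
directions encode the sign conventions the lobe rules need: left oblique
positive on the posterior-inferior side, right oblique positive
anterior-superior, right horizontal positive superior.

The tri-harmonic system — kernel ‖xᵢ − xⱼ‖³ bordered by the linear
polynomial block, right-hand side 0 on-surface and d off-surface — is
solved with a dense direct solve; if that is singular, a ridge of 10⁻⁸
on the kernel diagonal is added and the solve retried. Fitting happens
in voxel-index space (the subsampling grid, the cube and d are all
stated in pixels); the surface records the spacing so it can be
evaluated at mm coordinates. Interpolation is exact to 10⁻⁶ and the four
side conditions hold to 10⁻⁸ (tested against naive Gaussian
elimination).

**Lobe rules.** Right lung, first match wins: F₃ > 0 → upper;
F₂ > 0 → middle; else lower. Left: F₁ ≥ 0 → lower, else upper. Exact
zeros — a measure-zero set — resolve toward the inferior lobe. The
upper-lobe rule is applied literally even where F₃ > 0 but F₂ < 0; a
stricter conjunction can be had by evaluating the surfaces directly.

**Evaluation.** d_i = min_j ‖x_j^A − x_i^ref‖ from every reference point
to the algorithm surface — directional by design — summarized as mean ±
SD, RMS = √(Σd_i²/l) and max, in mm. The algorithm surface is
discretized by root-finding F along the z grid lines of the mask at
1-voxel (x, y) spacing with linear interpolation at sign changes. The
nearest-neighbour computation is the plain double loop, evaluated in
chunks, with the winning pair recomputed directly to avoid the
expanded-square precision loss.

## The phantom: what it emulates, what it does not

`phantomSpec()` describes a 96 × 128 × 128 voxel, 1 mm isotropic thorax:
two ellipsoidal lungs (−880 ± 20 HU i.i.d. Gaussian noise) in a 0 HU
body surrounded by −1000 HU air; fissure sheets 2 voxels thick at
−660 HU — brighter than parenchyma but below the −650 HU lung-band
ceiling, as fissures appear under partial-volume averaging; a
vessel-free margin of 5 voxels around every sheet; a branching vessel
tree (12 roots per hilum, four generations, radius 2 → 0.8 voxels) plus
small peripheral vessels on a jittered 8-voxel grid at +50 HU, dense
enough that scan lines away from a fissure reliably cross vasculature —
the anatomical premise SAFS relies on; and one 3-voxel emphysema blob
(−980 HU) in the left upper lobe. Fissure surfaces are graphs
z = c₀ + c₁(y − y_c) + c₂(y − y_c)², default planar with slope 0.9
(≈ 42°); the horizontal fissure exists only anterior to the oblique one,
where it actually separates the upper from the middle lobe. Truth lobes
apply exactly the lobe rules above to the analytic surfaces, and truth
surface samples satisfy their generating equation to machine precision.

Numerical detail: the default planes are placed off-lattice
(z₀ = 64.25, 80.3) so that no voxel row sits at F = 0 within machine
epsilon; with on-lattice planes the labels of whole rows become
floating-point coin flips, a lattice artifact with no physical meaning.

The phantom exercises every pipeline stage, but it is not a CT
simulator: no reconstruction texture or beam hardening, no airway tree,
no lobar shape variability, planar-to-quadratic fissures only, and its
lungs are roughly half the linear size of adult lungs. Passing the
phantom tests shows the machinery is correct and self-consistent under
the stated anatomy — it does not certify accuracy on clinical scans,
where fissure incompleteness, pathology and protocol differences
dominate. Two parameters are acquisition-bound and are rescaled by
`phantomConfig()`: `air_cut` (above) and the PFP grid spacing (30 px on
a 512-grid clinical lung ≈ 20 mm; 12 voxels on the phantom's smaller
lungs), without which the fissure would be supported by only ~3 centers.

Problem sizes used by the test-suite and the acceptance script: one
default 96 × 128 × 128 phantom (shared across tests), 50 random 12 × 12
cost grids plus 3–5 × 5 exhaustive instances for the tracer oracle,
64 × 64 slices for the enhancement oracle, 160 × 160 synthetic sagittal
slices at θ* ∈ {35°, 45°, 55°} for angle recovery, and RBF systems of
20–60 centers.

## Known limitations

* Accessory fissures and circular/irregular fissure morphology are out
  of scope; the straight-line scan model assumes a locally planar
  fissure at sagittal scale.
* The two sagittal slices are single points of failure: if SAFS locks
  onto the wrong band there, the whole fissure follows. The diagnostics
  (`sagittal_angles`, scores, `lowConfidence`) exist precisely so a user
  can verify this step cheaply; on small lungs the score contrast
  between the true band angle and oblique lines threading the same
  vessel-free corridor shrinks.
* RBF extrapolation beyond the detected fissure extent (e.g. the right
  upper/lower boundary posterior to where the horizontal fissure ends)
  is governed by the polynomial tail and degrades with noisy centers.
* The lung segmentation is deliberately simple and will not survive
  severe pathology (large consolidations, effusions); it is replaceable
  via precomputed masks.
* DICOM series are not read; convert to NIfTI or MetaImage first.
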