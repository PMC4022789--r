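# lobeseg — pulmonary fissure detection and lobe segmentation in chest CT

`lobeseg` implements an automatic pipeline that finds the three major
pulmonary fissures in a thoracic CT volume and partitions the lung field
into its five lobes. It is aimed at quantitative-imaging work where
per-lobe measures matter: lobar volumes, emphysema burden (LAA%), or
locating lesions by lobe.

## Method

The pipeline runs four stages, per fissure, on a volume in Hounsfield
units (canonical orientation: x right→left, y anterior→posterior,
z inferior→superior):

1. **Lung segmentation.** Voxels in the conservative acceptance band
   [−930, −650] HU are grown into 3D components; the two largest are the
   lungs. A 7 × 7 morphological closing on every axial slice fills vessel
   holes, a −300 HU threshold then removes vascular and airway-wall
   voxels, and the mask is split into left and right lungs.
2. **Sagittal adaptive fissure scanning (SAFS).** On the two sagittal
   slices at 40% and 60% of each lung's x extent, straight lines are
   scanned at angles θ (oblique 30–60°, horizontal −15–15°). A line is
   accepted when its lung intersection R exceeds r = 50 px and the
   longest vessel-free run L satisfies L/R > k = 0.6 — the fissure is the
   one band of parenchyma free of vessels and bronchi. Per angle, the
   accepted runs form connected regions; each candidate region is scored

   P = w₁·N′ + w₂·σ_R′ + w₃·R̄′,   (w₁, w₂, w₃) = (1, −1, 1)

   on z-standardized features (N scan lines, spread and mean of their
   in-region lengths), and the region with maximal P is the fissure
   region.
3. **Line enhancement and tracing.** Inside the fissure region the slice
   is enhanced with a multiscale Hessian (Frangi) bright-ridge filter;
   the cost image C = max(E) − E turns the ridge into a valley, and
   uniform cost search over the 8-connected pixel graph (edge cost =
   destination pixel) extracts the fissure line. The two sagittal lines
   give two marker points per coronal slice; a band of half-width 10 px
   around the marker line is traced the same way in every coronal slice,
   producing a 3D cloud of potential fissure points (PFP).
4. **Implicit surface fit and lobe labels.** The PFP cloud is subsampled
   on a sparse grid (points kept only when an 11³ cube holds > 80
   points), off-surface points are placed at d = 10 px along averaged
   local normals, and a tri-harmonic RBF surface

   F(x) = Σᵢ λᵢ ‖x − xᵢ‖³ + c₀ + c₁x + c₂y + c₃z

   is solved with F = 0 on-surface and F = d off-surface (plus the four
   side conditions Σλ = Σλx = Σλy = Σλz = 0). The signs of the three
   fitted surfaces F₁ (left oblique), F₂ (right oblique), F₃ (right
   horizontal) label every lung voxel: F₃ > 0 right upper; F₂ > 0 right
   middle; else right lower; F₁ ≥ 0 left lower; else left upper.

Accuracy is evaluated by shortest Euclidean distances from reference
surface points to the algorithm surface (mean ± SD, RMS, max, in mm).

Because no clinical volumes ship with the package, a seeded synthetic
thorax phantom (`generatePhantom`) provides full ground truth: ellipsoid
lungs at −880 ± 20 HU in a 0 HU body, fissure sheets at −660 HU with a
vessel-free margin, a branching vessel tree plus peripheral vessels at
+50 HU, and optional nodules and emphysema blobs.

## Worked example

```r
library(lobeseg)

ph  <- generatePhantom(phantomSpec(seed = 1))
res <- runPipeline(ph@volume, phantomConfig(ph@spec))

res$report
#>           lobe voxels volume_cm3  percent
#> 1   left_upper  80258     80.258 24.98101
#> 2   left_lower  81576     81.576 25.39125
#> 3  right_upper  39743     39.743 12.37036
#> 4 right_middle  40637     40.637 12.64863
#> 5  right_lower  79062     79.062 24.60875

algo <- sampleFittedSurface(res$surfaces$left_oblique,
                            maskArray(res$masks$left))
surfaceDistanceStats(algo, ph@truthSurfaces$left_oblique)
#> Surface distances (n=1931): mean 0.339 +/- 0.285, RMS 0.442, max 1.475 mm
```

The report rows are the five lobes with voxel counts, volumes in cm³ and
their share of the total lung volume; the distance summary is the
shortest distance from each ground-truth fissure point to the fitted
left oblique surface — here well under one voxel (1 mm). `res$laa`
holds the per-lobe emphysema index (LAA%: voxels < −950 HU among lung
voxels < −600 HU); the phantom's implanted emphysema blob makes the left
upper lobe the LAA% maximum. `res$diagnostics` records the SAFS slices
and angles, PFP counts and fit residuals for verification.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/lobeseg.R", package="lobeseg"))')" \
    phantom --seed 1 --out ph/
Rscript .../lobeseg.R run --in ph/volume.nii.gz --config ph/config.yaml --out seg/
```

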