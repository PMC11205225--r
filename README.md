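# conemosaic

Metrics of the living human foveal cone mosaic, and how reproducible they
are between visits.

Adaptive optics scanning light ophthalmoscopy (AOSLO) resolves single cone
photoreceptors in the fovea; after semi-automated cell marking, each imaged
region of interest (ROI) becomes a list of cone centre coordinates.  Groups
following patients with progressive retinal disease need the standard
summary metrics of that mosaic *and* their normal intervisit variability.
`conemosaic` implements the full pipeline from coordinates to cohort
reproducibility report, plus a synthetic mosaic generator with known ground
truth so every stage is testable.

## The metrics

For a cone field with Voronoi cells \(A_i\), density at a point is
estimated with an **adaptive square window**: the smallest axis-aligned
square (grown in whole-pixel steps) whose interior strictly contains the
Voronoi cells of at least *k* = 150 cones,

\[ \hat D = N_\mathrm{bound} \Big/ \sum_{i\in\mathrm{bound}} A_i
   \quad[\text{cones/mm}^2], \]

the bounded-Voronoi ratio, which is exactly \(2/(\sqrt3 s^2)\) on a
hexagonal lattice with spacing \(s\).  Evaluated over the ROI grid this
yields the **density matrix**, from which the pipeline extracts:

* **PCD** — peak cone density: location and value of the matrix maximum;
* **CDC** — cone density centroid: density-weighted centroid of the region
  at or above the 80th percentile of density (a grader- and visit-stable
  anchor for the foveal centre), with the density sampled there;
* the **80th-percentile isodensity contour area** and the **PCD–CDC
  offset**;
* linear (cones/mm²) and angular (cones/deg²) units, converted via
  Bennett's adjusted axial length model \(q = 0.01306\,(AL - 1.82)\)
  mm/deg.

Two visits of the same eye are compared by translating the visit-2 density
matrix so the CDCs coincide, subtracting over the overlap (**difference
map**), and extracting 5-µm-binned cross-section profiles through the CDC.
Cohort-level agreement uses percent change, Shapiro–Wilk normality of the
differences, paired *t*, Pearson correlation with Fisher-z intervals, and
Bland–Altman bias with 95% limits of agreement.

## Worked example

```r
library(conemosaic)

# synthetic foveal mosaic: peak 190,000 cones/mm^2, e-folding scale 120 um
fld <- generateMosaic(190000, 120, 300, seed = 7, axialLengthMm = 24)
fld <- rescaleToCommon(fld, 0.25)          # common grid, 0.25 um/px
dm  <- computeDensityMatrix(fld, k = 150, stride = 10)
fovealMetrics(dm)
#> FovealMetrics (subject 'synthetic', visit 1):
#>   PCD  172,000 cones/mm^2 at (150.1, 150.1) um
#>   CDC  172,000 cones/mm^2 at (150.2, 150.1) um
#>   PCD 14,400 / CDC 14,400 cones/deg^2
#>   80%-contour area 11,900 um^2 | PCD-CDC offset 0.127 um
```

The PCD reads ~172,000 rather than the planted 190,000 because the
150-cone window averages density over a ~30 µm square; with a 120 µm
falloff scale that attenuates the peak by about 10% — exactly as it does
on real data, where PCD is always a windowed estimate.  The CDC sits on
top of the peak (the mosaic is radially symmetric), so the offset is a
fraction of a micrometre; values are reported rounded to three significant
digits, reflecting image-scale uncertainty.

A full two-visit study in four lines:

```r
cohort <- generateCohort(19, seed = 1)      # two visits per subject
res    <- runCohort(cohort)                 # metrics + stats + profiles
res$stats$pcd_mm2$blandAltman               # bias and limits of agreement
res$report                                  # per-subject table, 3 sig. digits
```

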