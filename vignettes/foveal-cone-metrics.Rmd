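---
title: "Quantifying foveal cone mosaics: methods and design notes"
author: "conemosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying foveal cone mosaics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conemosaic)
```

## The problem

Adaptive optics scanning light ophthalmoscopy (AOSLO) resolves individual
cone photoreceptors in the living fovea.  After semi-automated cone
marking, each imaged region of interest (ROI) reduces to a list of cone
centre coordinates.  Clinical use of such data — following a patient with
a progressive retinal dystrophy, for example — requires summary metrics of
the foveal mosaic whose normal between-visit variability is known.  This
package implements the standard foveal density metrics and the
reproducibility analysis around them:

* the **density matrix**: cone density evaluated at every grid point of
  the ROI with an adaptive sampling window;
* **PCD** (peak cone density): the maximum of that matrix and its
  location;
* **CDC** (cone density centroid): the density-weighted centroid of the
  region at or above the 80th percentile of density — a spatially
  smoothed, more stable anchor for the foveal centre than the raw peak;
* the **80th-percentile isodensity contour area** and the **PCD–CDC
  offset**;
* two-visit **difference maps** aligned at the CDC, with binned
  cross-section profiles;
* cohort statistics: percent change, Shapiro–Wilk normality of the
  differences, paired *t*, Pearson correlation with Fisher-z intervals,
  and Bland–Altman bias with 95% limits of agreement.

## The density estimator

At a query point the estimator grows an axis-aligned square window in
whole-pixel increments until the window's interior strictly contains the
Voronoi cells of at least *k* = 150 cones; all vertices of a cell must lie
inside the window for it to count.  The density is then

$$\hat D = \frac{N_{\mathrm{bound}}}{\sum_{i \in \mathrm{bound}} A_i},$$

the number of contained cells over their summed Voronoi area.  Because
each Voronoi cell's area is the reciprocal of the local point density,
this ratio is exactly unbiased on a regular mosaic: for a hexagonal
lattice with spacing $s$ it returns $2/(\sqrt{3}\,s^2)$ regardless of the
window size.  (The naive alternative — contained-cell count divided by
*window* area — is biased low by roughly $4\delta/L$, with $\delta$ about
one cell radius and $L$ the window side, i.e. 15–20% at $k = 150$ and
foveal spacings, which is why the Voronoi-area denominator is the
convention in the cone-metrics literature and in this package.)

The window rule makes the estimator *adaptive*: windows are ~30 µm wide
at a 190,000 mm⁻² peak and widen as density falls.  One consequence worth
remembering: the estimate is an average over the window, so a local peak
narrower than the window is attenuated.  With an exponential density
falloff of scale $\lambda$, the windowed value at the peak is lower than
the true peak by roughly the mean of $e^{-r/\lambda}$ over the window —
about 10% at $\lambda = 100$ µm, under 3% at $\lambda = 400$ µm.  The
parameter-recovery tests that require the PCD to match a *planted* peak
value therefore use $\lambda = 400$ µm; the cohort simulations use the
steeper, anatomically realistic 90–140 µm range, where the PCD measures
the windowed peak, exactly as it does on real data.

A grid cell is *missing* (`NA`) when its smallest qualifying window would
cross the ROI boundary.  No edge correction is attempted; the
high-density foveal centre always sits in the valid interior, so the
trimmed border only removes low-density cells.

### Voronoi construction

No Voronoi/Delaunay library is part of this package's dependency
footprint, so the tessellation is built directly: each cone's cell starts
as a large box and is clipped against the perpendicular bisectors of its
neighbours in order of increasing distance.  Once every unprocessed
neighbour is farther than twice the current maximum vertex distance, no
further neighbour can cut the cell and the cell is exact — a certified
stopping rule rather than a heuristic neighbour count.  A cell is
*bounded* when all its vertices lie inside the ROI; only bounded cells
enter the density estimator.  The test suite checks interior cells against
the closed-form hexagon area and against cell areas frozen from an
independent computational-geometry implementation on a fixed point set.

### Numerical conventions

* **Window growth** is in whole-pixel increments of the common grid
  (default 0.25 µm/px); "contained" means all vertices strictly inside
  the window.  Monotone growth makes the smallest qualifying window
  unique.
* **Percentile threshold** is nearest-rank (the `ceiling(p/100 * n)`-th
  order statistic, no interpolation).
* **PCD ties** break deterministically to the smallest row, then column
  index.
* **CDC value** is sampled at the valid grid cell nearest the centroid
  (bilinear interpolation is available behind a flag).
* **Rounding** of reported values is to three significant digits,
  half-to-even, reflecting the uncertainty of the image scale
  calibration.
* **Angular conversion** uses Bennett's adjusted axial length model,
  $q = 0.01306\,(\mathrm{AL} - 1.82)$ mm/deg; it is isolated in
  `umPerDegree()` so another model can be swapped in.

## Comparing two visits

The acquisition protocol this pipeline mirrors crops a 300 µm ROI at the
first visit and a 500 µm ROI at the second; the larger revisit ROI exists
to tolerate fixation offsets, not to widen the analysis region.
`runCohort()` therefore analyses **both visits on a common 300 µm
window** (the centred crop of the larger ROI).  This matters for the
contour area: a nearest-rank percentile threshold makes the
80th-percentile region scale with the analysed area, so areas from
different ROI sizes are not comparable — on a common window they are.
It also means a subject whose two visits are identical produces exactly
identical metrics, an exact zero difference map, and a paired *t* of 0
(reported with *p* = 1 by convention), which the null-cohort tests
exploit.

Difference maps translate visit 2 by whole grid cells so the CDCs
coincide — no rotation, scaling, or subpixel interpolation (at 2.5 µm
cells the rounding is ≤ 1.25 µm) — subtract over the overlap, and crop to
300 µm about the CDC (to the overlap, with a warning, when a large
fixation offset shrinks it).  Cross-sections take the single row/column
through the CDC cell and tile it into contiguous 5 µm bins centred on the
CDC; composite profiles average the per-subject bin means and report the
across-subject SD and count per bin.

## The synthetic cohort generator

`generateMosaic()` warps a hexagonal lattice radially so the realised
local density is exactly $D(r) = P e^{-r/\lambda}$, then jitters
positions.  The construction gives closed-form oracles for density,
counts and local spacing.  Defaults for `generateCohort()` were chosen
once to emulate a healthy adult reproducibility cohort:

| parameter | default | rationale |
|---|---|---|
| peak density $P$ | U(175k, 240k) mm⁻² | windowed PCD estimates then centre near ~187k mm⁻² given the ~10% attenuation at $\lambda \approx 100$ µm |
| falloff scale $\lambda$ | U(90, 140) µm | density roughly fourfold lower at 150 µm eccentricity, matching foveal topography |
| packing jitter | 0.35 µm | ~0.14 of the peak spacing; keeps realised density within 2% of analytic |
| peak offset | ≤ 15 µm | the anatomical peak is not exactly at the ROI centre |
| axial length | N(23.91, 0.96) mm | sets per-subject pixel scale and angular conversion |
| interval | N(3.20, 0.51) yr, truncated 2.48–4.28 | used for interval-vs-change correlations |
| revisit | 15 µm translation SD, 1% scale-error SD, 0.3 µm jitter, 3% miss, 3% false | plausible magnitudes for fixation offset, calibration error and re-marking noise |

Translation and scale error are visit-2 acquisition effects; the marking
noise (jitter, misses, false detections) is applied independently to
*both* visits, because both visits' coordinates come from the same
marking process.  This symmetry matters: misses remove cones in
proportion to the local density while false detections are spatially
uniform, so marking noise applied to one visit only would plant a
systematic density bias at the fovea instead of the mean-zero
between-visit noise a reproducibility cohort should exhibit.

The revisit error rates are stipulations, not estimates — the marking
error process of real graders is not characterised here.  What the
generator deliberately does **not** emulate: reflectance variation and
image blur (coordinates are taken as given), anisotropic or elongated
packing, rod intrusion, and grader-specific systematic biases.  Passing
tests therefore demonstrate correctness of the *computations* on
realistic geometry, not robustness of cone *identification*.

A design detail that the null-cohort tests rely on: visit 1 is generated
as `cropConeField(master, 300)` — the same crop the pipeline applies to
visit 2 — and the pipeline crops at the native pixel scale before
rescaling.  A zero-perturbation revisit is the identity on coordinates,
so visit 2 then reproduces visit 1 *bit for bit*, and every paired
difference is exactly zero.  Without this, "no change" cohorts would
produce iid numerical noise and the paired-*t* p-value would be uniform
rather than 1.

## Simulation sizes and degenerate inputs

The validation suite runs uniform-lattice checks at five densities
spanning 150k–220k mm⁻², twenty single-peak recovery seeds, a 19-subject
null cohort, and fifty 8-subject replicates for the planted-bias
(5% multiplicative density change) recovery check — sizes chosen to give
tight checks at interactive runtimes on one CPU.  Density grids in the
tests use strides of 12–24 px (3–6 µm); the estimator itself is
stride-consistent (a coarse grid equals the subsampled fine grid), so
stride trades resolution of the *argmax* locations, not accuracy of the
values.

Degenerate inputs are rejected early with specific errors: duplicate
coordinates (they break the tessellation), collinear point sets, fields
with fewer cones than *k*, percentile regions with fewer than 5 valid
cells, zero-variance vectors in the normality and correlation tests.
Zero-variance *paired differences* are the one deliberate exception —
identical visits are a meaningful outcome (`t = 0`, `p = 1`), and a
constant nonzero difference reports `t = ±Inf`, `p = 0`.

Two small systematic effects are visible in default synthetic cohorts
precisely because the generator's between-subject variance is far smaller
than real data's.  First, the uniform false-detection model adds spurious
points at a rate proportional to the ROI's cone count, so the smaller,
fovea-centred visit-1 ROI receives a slightly higher false-point
*density* than the 500 µm visit-2 ROI — about `falseRate` times the
difference of the two ROIs' mean densities, i.e. ~1% of peak density.
Second, a fixation offset shifts the analysable interior of the visit-2
window down the density falloff, trimming a fraction of a percent from
its valid area and hence its contour area.  Both effects are small
fractions of the limits of agreement; against the much larger
between-subject variance of real cohorts they would be undetectable, but
a paired *t* on nearly noise-free synthetic metrics can flag them.

## Known limitations

* The radial warp that makes the generator's density profile exact also
  makes its packing radially anisotropic far from the peak (tangential
  and radial spacings diverge for $r \gg \lambda$); local density is
  still exact, but nearest-neighbour distances out there fall below the
  isotropic-equivalent spacing $\sqrt{2/(\sqrt{3} D(r))}$.
* The PCD–CDC offsets of the synthetic cohort (~2–5 µm) are smaller than
  typical real-data offsets (~10–15 µm): real foveal topography has local
  asymmetries and multi-lobed peaks that the radially symmetric generator
  does not model.  Offset *reproducibility* machinery is unaffected.
* Between-visit analysis assumes pure translation; real revisits can
  include small rotations and non-rigid residual distortion.
* The contour area depends on the analysed window size by construction
  (rank percentile); compare areas only across equal-sized windows.
* Angular units depend on the axial-length model; switching conventions
  rescales angular densities by a constant per subject.
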