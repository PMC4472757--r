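---
title: "Quantifying carotid lumen remodeling: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying carotid lumen remodeling: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumenprof)
```

## The problem

In the murine partial carotid ligation model, disturbed flow in the left
common carotid artery (LCCA) drives progressive lumen loss, while the right
carotid (RCCA) serves as an internal control. Quantifying that loss
longitudinally requires measuring the open lumen along the artery, from the
aortic arch to the bifurcation, in contrast-enhanced micro-CT volumes — and
validating those measurements against the histological gold standard, which
is itself distorted by fixation shrinkage and embedding compression.

`lumenprof` implements the full measurement chain for both modalities plus
the statistics that compare them, and ships a synthetic phantom generator so
that every stage can be exercised against known ground truth without animal
data. No public scans accompany the original study, so the phantom is the
package's test bed: all quantitative claims in the test suite are claims
about recovery of synthetic truth, not about animal data.

## The CT measurement chain

**Calibration and segmentation.** Two regions of interest — one in the
contrast-filled blood pool, one in muscle — give mean intensities whose
midpoint is the segmentation threshold:
$T = (\mu_{\text{blood}} + \mu_{\text{muscle}})/2$. The lumen mask is the
set of voxels at or above $T$, restricted to the 26-connected component
containing a user seed, so that adjacent contrast-filled structures are
excluded. 26-connectivity is used because thin oblique vessels fragment
under 6-connectivity at 18 µm voxels. No morphological post-processing is
applied by default (a closing radius is available but off).

Threshold placement is the dominant accuracy lever: the mask surface sits
where the blood-to-surroundings partial-volume ramp crosses $T$, so any
offset between $T$ and the ramp's half-occupancy level displaces every
radius by a proportional fraction of a voxel. The segmentation tests
verify that the sign of the diameter bias flips as the threshold crosses
the half-occupancy level.

**Tracing (the virtual elastic sphere).** Between two seed points — placed
just distal to the aorta and just proximal to the bifurcation — the tracer
finds, among all 26-neighbour voxel paths through the mask, the path
minimizing the radius-weighted length $\sum \mathrm{step}/r$, where $r$ is
the inscribed-sphere radius from an anisotropy-aware Euclidean distance
transform. This is our realization of the interactive "elastic sphere"
measurement: a maximally inflated sphere sliding between the seeds hugs the
medial axis, and narrow or off-centre voxels are expensive. The original
tool's algorithm is not published; the radius-weighted geodesic is an
interpretation that reproduces its described behaviour, and the tests pin
it down by comparing against exhaustive search on small masks.

Two numerical refinements matter at vessel calibres of 8–30 voxels:

* the discrete voxel path cannot express sub-voxel axis positions, so the
  per-point radius is re-estimated by letting the sphere centre slide on a
  small grid in the plane perpendicular to the local path tangent
  (±1 voxel in steps of a quarter voxel) and inflating it against actual
  background voxel centres;
* the traced polyline is smoothed with a 3-point moving average (endpoints
  fixed) before arc lengths are accumulated, removing the stair-step
  inflation of path length.

Equal-cost path ties are broken toward the smaller linear voxel index, so
traces are deterministic. Seeds given in mm snap to the nearest mask voxel
within a 5-voxel ball. A radius at or below one voxel anywhere on the path
raises a near-occlusion warning.

**Profiling.** Because carotid length varies between animals, arc length is
normalized to $[0,1]$ and partitioned into nine equidistant segments
(segment 1 at the arch, 9 at the bifurcation); nine matches histological
sectioning every 500 µm along a ≈4.2 mm carotid. Sampled diameters are
arithmetically averaged within each segment — the diameters are grouped and
averaged first, then converted — and the segment area assumes a circular
cross-section, $A = \pi \bar d^2/4$. `n_segments` is a parameter; 9 is the
default everywhere.

## The histology measurement chain

Section-level lumen estimation never uses raw planimetric area of the lumen
contour, because paraffin embedding compresses the vessel: a collapsed
lumen loses area but barely loses perimeter. The rule is always
perimeter-based: $d = P/\pi$, $A = P^2/(4\pi)$. For diseased sections the
pre-disease lumen circle is reconstructed from the perimeter of the inner
layer of the tunica media and the planimetric plaque area is subtracted;
negative results clamp to zero with a warning. Plaque area is consumed as
an annotated number, not segmented from images. One consequence the tests
make explicit: for any non-circular contour the perimeter rule
overestimates planimetric area (the isoperimetric inequality), which is the
price of robustness to compression.

Nine sections map index-to-segment when exactly nine exist; otherwise
positions are normalized and assigned to the nearest of nine equidistant
bin centres, with missing segments reported as `NA`. Whether the original
analysis index-matched or position-matched is unstated; both paths exist
and the index-matched one is used when counts allow.

## The phantom generator

The phantom emulates contrast-enhanced neck CT around a curved, stenosed
vessel with known truth:

* **Geometry.** The centerline is a Catmull-Rom spline through control
  points, arc-length resampled at half-voxel steps (carotids do not run
  straight in the neck, so curvature must be representable). Local diameter
  is a base calibre modulated by raised-cosine stenoses; severity $s$
  narrows the diameter to exactly $(1-s)$ at the stenosis centre and stays
  below 1 — the lumen never fully occludes, as in partial ligation. The
  default length is 4.2 mm so that sections every 0.5 mm give nine.
* **Solid.** The vessel solid is a generalized surface of revolution: a
  point is inside when its distance to the nearest centerline sample is
  within that sample's radius. (A union-of-spheres model was rejected: with
  rapidly varying radius the wide neighbouring spheres bulge into a
  stenosis throat and break the true-diameter semantics.) A short stump of
  1.5 local radii is rendered beyond each centerline end, because in vivo
  the artery continues past both seed points; without it the end-cap
  background clips the inscribed spheres in the first and last segments.
  Truth tables cover the seeded span only.
* **Image formation.** Voxel occupancy is supersampled 3×3×3 against the
  solid, mapped linearly from background to blood intensity, convolved with
  an isotropic Gaussian point-spread function, and degraded with seeded
  Gaussian noise. Noise is Gaussian rather than Poisson because the
  published calibration is a mean ± SD in arbitrary units, which fixes only
  second moments. A cuboid of muscle intensity sits a fixed 10 voxels from
  the vessel to provide the soft-tissue calibration ROI (the original
  muscle ROI geometry is undescribed, so it is fixed by convention here).
* **Default scene.** In vivo: blood 148.3 units with noise SD 2.0 at 18 µm
  isotropic voxels; ex vivo: blood 155.8, noise SD 1.6, 9 µm. Muscle is not
  published and defaults to 100, well below the enhanced blood pool. The
  ambient background defaults to 90 — unenhanced perivascular soft tissue
  just below muscle — because in a neck scan the vessel wall borders
  tissue, not air; this also places the blood/muscle midpoint threshold
  near the half-occupancy point of the wall's partial-volume ramp, which is
  precisely the situation the midpoint rule is designed for. The PSF sigma
  defaults to one voxel, a realistic effective blur at the scanner's
  nominal resolution.
* **Virtual histology.** Sections are cut perpendicular to the true
  centerline every 0.5 mm. Each lumen circle is scaled by a shrink factor
  (default 0.77, making areas ≈1.7× smaller, the magnitude reported for
  fixation/embedding shrinkage) and optionally mapped to an
  equal-perimeter ellipse with axis ratio ≥ 1 at a seeded random
  orientation, emulating embedding compression. The equal-perimeter
  construction is exact up to quadrature: perimeter scales linearly, so the
  ellipse is a single rescale of the unit shape whose perimeter is
  integrated numerically. Plaque, when configured, is a fraction of the
  shrunken media-circle area.

What the phantom does **not** emulate: X-ray physics (beam hardening,
dose), motion and gating artefacts, stained-tissue texture, bifurcation
geometry, or non-elliptical section distortion. Passing recovery tests on
phantoms therefore demonstrates the correctness of the measurement chain,
not the image quality of any particular scanner.

## Agreement statistics

Per-vessel mean lumen areas from two modalities are compared by ordinary
least squares (micro-CT as response, histology as predictor, matching the
presentation of the original comparison; the direction is configurable),
with Pearson's $r$ and its two-sided $t$-test on $n-2$ degrees of freedom,
and by Bland-Altman analysis: bias = mean difference, limits of agreement =
bias ± 1.96 SD of the differences (sample SD). The 1.96 multiplier is fixed
by convention. Per-timepoint correlations reuse the same regression within
groups, skipping groups under three pairs with a warning.

Group comparisons across postoperative timepoints use a one-way ANOVA on
per-animal mean areas (segments averaged per animal first) followed by all
pairwise pooled-SD t-tests with Bonferroni adjustment; per-segment
comparisons between groups use unadjusted equal-variance two-sided t-tests,
reported segment by segment. Equal-variance is chosen because the source
analysis specifies a Student test without further qualification.

## Numerical choices and degenerate inputs

* Voxel indices are 1-based in R; world coordinates are mm at voxel
  centres. All distances, diameters and areas are mm-based throughout.
* The distance transform treats out-of-grid voxels as background, so masks
  touching the volume border are not implicitly extended.
* NIfTI headers store voxel spacing as 32-bit floats; spacing is snapped to
  7 significant digits on read, and round-trip tests hold to better than
  1e-9 mm.
* Equal calibration means raise a degenerate-contrast warning and the
  threshold equals that value; overlapping ROIs warn; empty ROIs error.
* `bin_profile` refuses sparse traces that would leave a segment empty,
  instructing denser resampling rather than silently interpolating.
* A single-vessel "group" reports SEM 0 with a warning; all-zero
  within-group variance makes the ANOVA F degenerate and errors.
* Self-intersecting section contours are rejected; zero-area contours warn.
* Plaque exceeding the reconstructed media circle clamps lumen area to 0
  with a near-occlusion warning.

## Problem sizes in the tests and acceptance script

The test suite exercises full-scale scenes only where needed: tracing
optimality is proven exhaustively on ≤8³ masks (50 cases), diameter
recovery on twenty 4.2 mm phantoms spanning 8–30 voxel calibres at 18 µm,
the shrinkage-slope experiment on twelve vessels at the 9 µm ex vivo
resolution, statistical calibration on 2000 null ANOVA replicates and 10⁴
Bland-Altman pairs, and the bundled demo on five mice per modality at full
printed resolutions (18 µm and 9 µm). These sizes were chosen as the
smallest that make each property sharp; all are seeded and deterministic.

## Known limitations

* The elastic-sphere reading at a steep stenosis shoulder is bounded by the
  oblique wall and reads below the local cross-section diameter — a
  property of any maximal-inscribed-sphere method, shared with the
  interactive tool it models. Gentle, physiologically plausible stenosis
  extents keep this effect within a fraction of a voxel.
* The midpoint threshold is exactly the published rule; when the tissue
  surrounding a vessel differs in intensity from the muscle ROI used for
  calibration, the rule carries a proportional sub-voxel surface offset.
  The phantom defaults make this offset small but deliberately non-zero.
* Exactly one path per trace: no bifurcation detection or tree extraction.
* Histology consumes contours and plaque annotations; it does not segment
  micrographs.
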