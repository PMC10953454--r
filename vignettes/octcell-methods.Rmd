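---
title: "From macular OCT thickness to retinal cell densities: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From macular OCT thickness to retinal cell densities: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octcell)
```

## The problem

Optical coherence tomography (OCT) measures retinal layer thickness in
vivo, while cell densities — ganglion cells (GC), the inner nuclear layer
(INL) populations, photoreceptors — are known only from ex vivo histology
of a handful of donor eyes. If layer thickness is to stand in for cell
number in clinical and research use, two gaps must be closed: thickness
must be measured finely and correctly (commercial software averages over
coarse subfields and measures axially, ignoring B-scan tilt), and the
demographic structure of a thickness dataset must be modeled so that an
OCT cohort can be brought to the age and composition of the histological
cohorts before densities are transferred.

`octcell` implements that pipeline end to end:

1. **Tilt-corrected extraction**: perpendicular layer thickness from
   segmented boundary volumes, averaged onto a 60 × 60 grid of
   114.67 μm squares spanning 6880 μm around the fovea (a 56.25-fold
   denser sampling than the standard 8 × 8 grid), in right-eye format.
2. **Demographic models**: multiple linear regression of whole-macula
   mean thickness on age, refraction, sex, ethnicity and acuity, with the
   10% age-coefficient comparison rule and backward elimination of
   nonsignificant covariates.
3. **Cluster aging models**: hierarchical clustering of grid squares by
   their decade-binned thickness profiles, pooled until every cluster
   pair is statistically separable, then per-cluster quadratic or linear
   aging models with inflection ages and annual percentage rates.
4. **Cohort correction and agreement testing**: additive age (and
   covariate) correction to a reference age-equivalent, validated with
   Hodges–Lehmann/Mann–Whitney comparisons and Bland–Altman analysis.
5. **Histology linkage**: meridian density profiles interpolated over the
   grid, converted between areametric (cells/mm²) and volumetric
   (cells/mm³) form via layer thickness, an equivalent-cone packing model
   for photoreceptors, and per-region cell-count prediction.
6. **A synthetic-cohort generator** with known ground truth, so every
   stage is testable without clinical data.

## Tilt-corrected thickness

B-scan tilt is estimated at each A-scan as the angle of the local tangent
to the retinal pigment epithelium (RPE): a least-squares line through a
centered window of RPE positions, computed in physical units (lateral and
axial pixel scales applied before the arctangent). The default window is
21 A-scans; the published description ("the tangent along each location")
fixes no scale, and a windowed fit is noise-robust while leaving the
estimate locally exact for straight or gently curved RPE. Locations with
fewer than a full window of finite samples are invalid.

Layer thickness is the distance along the normal to that tangent between
its intersections with the layer's inner and outer boundary curves,
multiplied into micrometers. The intersection is solved by fixed-point
iteration `t ← (v0 − c(u0 + t·sinθ))/cosθ` on the piecewise-linear
boundary curve `c`; the iteration contracts whenever
`|c′·tanθ| < 1`, which holds comfortably for slab-like anatomy at the
tilts seen in macular scans (≤ 40°). For a uniformly tilted slab the
result equals the axial separation times `cos θ` exactly, and the
percentage error of the uncorrected axial measure is `100(cos θ − 1)` —
about −5% at 18.2° of tilt, which is why correction matters even for
nominally flat macular acquisitions. An `"axial"` extraction mode is
provided to reproduce the uncorrected measure for tilt-effect analyses.

Extraction places each A-scan at its en face offset from the fovea,
rotates by the fovea-to-disc axis angle supplied in the scan geometry,
mirrors left eyes into right-eye format (columns read temporal → nasal),
and averages valid samples per square. Squares are invalidated by the
exclusion mask (vessels, optic nerve head), by B-scans under the 15 dB
signal-quality cutoff, or when they contain fewer than `min_samples`
(default 1) valid samples. With 61 B-scans spaced 120 μm and 114.67 μm
squares, roughly 3 of 60 grid rows contain no B-scan center and are
legitimately invalid; downstream code carries the validity mask rather
than imputing.

## Cluster pooling and aging models

Participants are binned by decade (20–29 … 60–69, with 70+ pooled), and
each grid square is summarized by its vector of per-bin mean thicknesses.
Squares are clustered agglomeratively under squared Euclidean
dissimilarity with *within-groups linkage*: each step merges the pair
whose union has the smallest mean within-cluster pairwise dissimilarity.
We implement this directly through the identity
`Σ_{i<j}‖x_i−x_j‖² = n·SS` (SS the total squared deviation from the
centroid), which gives an O(n²) algorithm maintaining centroids and SS;
UPGMA average linkage on squared distances is available as a flagged
fallback. Ties resolve to the lowest cluster index, so runs are
deterministic.

The initial cut at `k0` clusters (default 15) is deliberately generous:
a pooling loop then repeatedly merges the least-separable failing pair —
lowest d′ first, ties broken by smaller mean difference — until every
surviving pair satisfies both criteria:

* `d′ = |x̄₁ − x̄₂| / √(0.5(σ₁² + σ₂²)) ≥ 1` (one pooled SD), and
* `|x̄₁ − x̄₂| ≥ 3.87 μm` (one axial pixel).

Cluster statistics are computed over the member squares' decade-bin means
(the clustered feature values). Because pooling continues to a fixed
point, the final partition is insensitive to moderate changes in `k0`;
this is property-tested for `k0 ∈ {10, 15, 20}` on planted nine-ring
fields. Final labels are renumbered by increasing mean thickness.

Per cluster, observations are pooled as (bin abscissa, per-square bin
mean) pairs and both a linear and quadratic model are fit, compared by
the extra sum-of-squares F test
`F = ((SSE_lin − SSE_quad)/1)/(SSE_quad/(n−3))` at α = .05. Two numerical
choices matter here and were made after measurement:

* **Abscissa**: each bin's *empirical mean participant age*, not the
  nominal decade midpoint. The bin-mean thickness reflects the ages
  actually sampled; with midpoints, cohort age-sampling error enters all
  squares coherently and the pooled fit's coefficient confidence
  intervals become anticonservative (planted-truth coverage fell to
  ~75%). The 70+ bin has no midpoint in any case.
* **Quadratic regressor**: the bin's empirical mean of age², not the
  squared mean age. The expectation of a quadratic over a bin involves
  the within-bin second moment; with the naive `x²` regressor the
  open-ended 70+ bin leaves a deterministic residual term and coverage
  stays near 85–90%. With both corrections the binned fit is exactly
  linear in its regressors and measured coverage is ~95–97%. When the
  function is called on raw (unbinned) ages it reduces to the ordinary
  quadratic fit.

For quadratic fits the inflection age `x = −b/(2a)` marks the peak and
onset of decline. The annual percentage rate over an age range
`[lo, hi]` (default 20–85 y) is referenced to the peak predicted
thickness `P` attained at age `a*`:
`100·(pred(hi) − P)/(P·(hi − a*))` %/y. For models whose peak sits at
`hi` (non-declining), the rate is referenced to the range start instead,
`100·(pred(hi) − pred(lo))/(pred(lo)·(hi − lo))`; a constant model rates
0. Published tables of this quantity are not exactly reproducible from
their rounded coefficients, so the definition is documented here and
exercised against models whose behavior is unambiguous.

## Cohort correction and the agreement battery

Correction is additive: a square in cluster `k` observed at age `A` is
shifted by `model_k(ref_age) − model_k(A)`, plus
`estimate·(ref_value − value)` for each corrected covariate (e.g. INL sex
and refraction effects, with reference values taken from the age-similar
subcohort). The agreement battery between square-wise cohort summaries
(medians per square by default, since the published difference maps are
per-location) computes: the Hodges–Lehmann median of pairwise differences
with its CI and an unpaired Mann–Whitney test; Bland–Altman bias and
1.96-SD limits of agreement; an OLS regression of difference on mean with
its F test and R²; the 95% prediction-interval width evaluated at the
midpoint of the observed mean range (the width varies along the axis and
a single scalar is reported); and the maximum predicted difference,
`max|fitted| + PI width/2`.

One caution for interpreting the limits of agreement: for approximately
normal differences the fraction of points inside the 1.96-SD limits
concentrates at 95.0% by construction, so that fraction measures the
estimator, not the correction. The meaningful acceptance logic — applied
in this package's validation — is that the bias and both limits of
agreement fall within the instrument's 3.87 μm axial pixel, and that at
least 95% of per-square differences lie within that axial-resolution
band.

## Histology linkage

Meridian density profiles (temporal, superior, nasal, inferior; right-eye
convention T = 0°, S = 90°, N = 180°, I = 270°) are resampled radially at
5 μm and interpolated *linearly in angle* between flanking meridians.
Grid squares average the polar field over a ≥ 23 × 23 sub-lattice
(≈ 5 μm spacing); squares reaching beyond a profile's radial support are
invalid rather than extrapolated. Volumetric density is areametric
density divided by thickness in mm, and the two conversions round-trip to
1e−9 by construction.

INL component densities (amacrine, bipolar, horizontal, Müller cells,
each a sum of decaying exponentials in eccentricity) are summed, divided
by `1 − 0.106` to account for the fraction of INL cells unlabeled by
DAPI, and expressed as proportions of the corrected total — proportions
therefore sum to 0.894, and the grids returned include the unlabeled
remainder so the decomposition is exactly conservative. Because the
component data exist only for the temporal meridian, volumetric INL
density is computed there (against the temporal thickness profile, taken
from the two central grid rows) and extrapolated as a function of radius
alone; multiplying back by the full thickness grid reintroduces the
retina's nasal-temporal asymmetries in the areametric maps.

Photoreceptors co-stratify, so the inner/outer segment layer is linked
through an *equivalent-cone* model assuming maximal hexagonal packing:
with `w` the flat-to-flat inner-segment diameter, the cross-section area
is `(√3/2)w²`. Cone diameters are Akima-splined onto the 5 μm grid
(nearest-value extension outside the supplied samples); cone coverage
`f_c = cone_density × A(w_c)` is clamped to 1, with coverage above
1.02 treated as inconsistent input. The remaining area is shared among
rods, `A_r = (1 − f_c)/rod_density`, giving a raw rod diameter
`w_r = √(2A_r/√3)`; since sparse central rods make this ratio unstable,
`w_r` is replaced by its linear-in-eccentricity OLS fit excluding points
within 300 μm of center. Equivalent cone density *adds* the
area-converted rods, `cone + rod·A_r^fit/A(w_c)` (the alternative —
replacement — is not used; the additive convention is flagged here), and
equals the cone density inside the rod-free zone (configurable radius,
default 150 μm, constrained to the reported 126–200 μm range). Cell
counts over a region follow as
`Σ volumetric × thickness(mm) × square_area(mm²)`.

## The synthetic-cohort generator

The generator encodes a ground-truth model — an en face cluster label
field (concentric rings by default), per-cluster quadratic aging
coefficients `c + b·age + a·age²`, additive sex/refraction effects
(applied to the INL by default), participant-level offsets, measurement
noise, and a global B-scan tilt — and renders it two ways:

* **Rendered boundary volumes**: five boundary surfaces per B-scan built
  by perpendicular offsetting from a planar-tilted (or spherical, for
  stress tests) RPE, so the perpendicular separation between bounding
  surfaces equals the true thickness exactly. Boundaries are continuous
  (sub-pixel) by default so oracle tests can be exact; a quantize flag
  rounds to whole 3.87 μm pixels to emulate discrete segmentation.
* **Fast grid-level cohorts**: per-participant thickness grids drawn
  directly from the truth field with square-level i.i.d. noise,
  bypassing rendering. This is the workhorse for statistical validation
  at cohort scale.

Default demographics emulate a healthy adult clinic population: ages
uniform on 20–85 y, refraction −0.5 ± 1.75 D truncated to the
+3 to −6 D inclusion range, balanced sex, a White/Asian mix and
near-zero logMAR acuity. Measurement noise defaults to 2 μm and the
participant-level offset to 2 μm; noise is i.i.d. by default because the
spatial correlation of real segmentation error is not characterized —
smooth-field structure can be emulated through the label field instead.

What the generator does *not* emulate: raster reflectivity (speckle,
shadowing), segmentation failure modes, foveal pit shape variation,
axial-length magnification, or spatially correlated noise. Passing tests
therefore demonstrate the correctness of the geometry, statistics and
bookkeeping under the stated model, not robustness to every artifact of
clinical data.

## Validation problem sizes

The test suite validates with: slab phantoms at tilts to ±40°
(perpendicular recovery to 1e−6 μm); planted three-band and nine-ring
partitions (exact cluster recovery, separability invariant, `k0`
insensitivity) at the full 60 × 60 grid; 100 replicate cohorts of
n = 250 with 2 μm noise on a 30 × 30 grid for coefficient-recovery
coverage (the finer grid adds squares, not information, to a
cluster-level fit, and the coarser field keeps the replicate study
compact) with ≥ 90% CI coverage per coefficient and inflection recovery
within ±3 y (measured ≲ 1.5 y); and a correction round-trip from a
40-eye naive cohort (ages 20–25 and 60–65) against a 27–40 y age-similar
reference, with bias and limits of agreement well inside one axial
pixel.

## Limitations

* Transverse magnification with axial length/refraction is not
  corrected; highly myopic eyes would need it.
* Fovea and disc positions are taken from scan metadata; automatic
  detection is out of scope.
* The histological linkage inherits its sources' limits: few donors,
  narrow age ranges, meridians only (GC, photoreceptors) or a single
  meridian (INL), and the packing model's hexagonal idealization, which
  is known to overestimate central rod diameter (hence the regression
  guard).
* Aging models are cross-sectional; longitudinal change in an individual
  need not follow them.
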