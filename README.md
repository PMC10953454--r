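# octcell

Retinal cell density estimation from high-density macular OCT thickness
maps.

Retinal layer thickness from optical coherence tomography (OCT) is widely
used as a stand-in for the number of cells in that layer, but the two have
rarely been linked quantitatively: commercial software averages thickness
over a few coarse subfields, measures it axially (ignoring B-scan tilt),
and histological cell densities come from small donor cohorts of a
particular age. `octcell` implements, as a tested and reusable pipeline,
the process of building normative demographics-corrected spatial models of
macular GCL, INL and ISOS thickness and linking them to histological
density profiles, so that areametric (cells/mm²) and volumetric
(cells/mm³) densities — and per-region cell counts — can be computed for
an individual eye.

The pipeline, for users in vision science and ophthalmic imaging research:

- **Tilt-corrected extraction** — thickness is measured along the normal
  to the local tangent of the retinal pigment epithelium (perpendicular,
  not axial: for a slab tilted by θ the axial measure errs by
  `100(cos θ − 1)` %, about −5% at 18°), then averaged onto a 60 × 60
  grid of 114.67 μm squares over the central 6880 μm (a 56.25-fold
  denser sampling than the standard 8 × 8 grid), in right-eye format.
- **Demographic models** — OLS regression of mean macular thickness on
  age, refraction, sex, ethnicity and acuity; the 10% rule comparing the
  age coefficient between multiple and age-only regression; backward
  elimination to corrected covariate estimates.
- **Cluster aging models** — grid squares are clustered on their
  decade-binned thickness profiles (squared Euclidean, SPSS-style
  within-groups linkage) and pooled until every pair of clusters is
  separable by `d′ = |x̄₁−x̄₂|/√(0.5(σ₁²+σ₂²)) ≥ 1` **and** a mean
  difference of at least one axial pixel (3.87 μm). Each cluster gets a
  quadratic or linear aging model (extra sum-of-squares F test), an
  inflection age `x = −b/(2a)` and an annual percentage rate of change.
- **Cohort correction** — additive correction to a reference
  age-equivalent (plus sex/refraction shifts), validated by a
  Hodges–Lehmann / Mann–Whitney / Bland–Altman agreement battery with
  prediction intervals.
- **Histology linkage** — meridian density profiles interpolated at 5 μm
  and averaged per grid square; areametric ↔ volumetric conversion
  through layer thickness; INL component decomposition with the 10.6%
  DAPI-unlabeled correction; an equivalent-cone photoreceptor model
  assuming hexagonal inner-segment packing; cell-count prediction.
- **Synthetic cohorts** — a ground-truth generator (boundary volumes with
  controllable tilt and noise, demographics tables, meridian profiles) so
  the whole pipeline is testable without any clinical data.

## Worked example

Generate a synthetic 250-eye cohort with three planted concentric aging
regimes, fit the cluster aging models, and derive a ganglion-cell
volumetric density map from a ring-shaped meridian density profile:

```r
library(octcell)
set.seed(2026)

truth <- ground_truth_model("GCL",
  clusters = list(c(-0.0010, 0.08, 19.80),   # a, b, c per cluster
                  c(-0.0023, 0.18, 27.79),
                  c(-0.0034, 0.25, 37.88)),
  ring_radii_um = c(1200, 2400, 5000),
  noise_sd_um = 2, between_sd_um = 2)
demo  <- generate_demographics(250)
grids <- generate_thickness_grids(demo, truth)

cm <- cluster_aging_models(grids, demo, k0 = 15)
cm
#> Cluster model (GCL): 3 separable clusters over 3600 squares
#>   cluster 1: mean 21.19 um, sd 0.78, n 1992; quadratic a=-0.001459 b=0.121 c=19.3 (x=41.3 y, -0.29 %/y)
#>   cluster 2: mean 30.50 um, sd 1.41, n 6288; quadratic a=-0.002758 b=0.22 c=27.31 (x=39.9 y, -0.39 %/y)
#>   cluster 3: mean 40.98 um, sd 2.18, n 13320; quadratic a=-0.003831 b=0.287 c=37.47 (x=37.5 y, -0.42 %/y)
```

The three planted regimes are recovered as three separable clusters; the
fitted quadratic models put the onset of age-related GCL decline
(inflection `x`) between 37.5 and 41.3 years with annual rates of −0.3 to
−0.4 %/year relative to peak thickness. Linking a GC meridian density
profile to the age-similar (27–40 y) mean thickness grid then gives a
volumetric density map and cell counts:

```r
gc    <- generate_meridian_profiles("GC")   # or read published data (CSV)
areal <- grid_average_density(interpolate_between_meridians(gc),
                              cell_class = "GC")
sim <- demo$age_years >= 27 & demo$age_years <= 40
ref <- thickness_grid(Reduce(`+`, lapply(grids[sim],
                                         function(g) g$values_um)) /
                        sum(sim), "GCL")
vol <- to_volumetric(areal, ref)
vol
#> GC volumetric density grid (cells/mm3): 3600/3600 valid, peak 1.73e+06

predict_cell_count(ref, vol)
#> [1] 375387.4
#> attr(,"coverage")
#> [1] 1
```

i.e. a peak volumetric GC density of 1.73 × 10⁶ cells/mm³ and an
estimated 3.8 × 10⁵ ganglion cells over the central 6.88 mm square of
this synthetic macula. Published histological tables (GC and
photoreceptor densities per principal meridian, INL sum-of-exponential
components, cone diameters) can be supplied in the same CSV schema via
`read_meridian_profiles()` in place of the generator.

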