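# bctdensity

Quantitative breast composition analysis for dedicated spiral breast CT
(BCT). BCT images the pendant breast of a prone patient in true 3D at
(300 µm)³ voxels; the Hounsfield-unit (HU) contrast between adipose
(≈ −100 HU) and fibroglandular tissue (≈ +40 HU) makes the breast's
composition directly measurable. `bctdensity` implements the measurement
chain end to end, for radiology researchers and medical physicists who
need volumetric density estimates — e.g. for breast-cancer risk modelling
or for checking the 50% density assumption built into mammographic dose
coefficients:

* **Segmentation** of each volume into air, adipose, gland, skin,
  pectoralis muscle, rib and skin-fold classes. The glandular class is
  delineated by an *adaptive region growing* algorithm: voxels are mapped
  to a glandular fraction `g = clamp((HU − µ_fat)/(µ_gland − µ_fat), 0, 1)`,
  high-`g` voxels seed the region, and neighbours are accepted while
  `g ≥ max(floor, α·(1 − D))`, where `D` — the running average breast
  density — is recomputed from the grown region after every sweep.
* **Quadrant localization**: the nipple is the centre of mass of the skin
  in the most posterior slice; two perpendicular planes through it split
  the breast into the UOQ/UIQ/LOQ/LIQ clinical quadrants.
* **Features**: breast tissue volume (BTV, cm³), mammary gland volume
  (MGV, cm³) and percent breast density (PBD, %) — HU-fraction based and
  volumetric — per breast and per quadrant, with quadrant shares.
* **Cohort statistics**: 5-year age-group summaries (ages 40–74), pooled
  Student t comparisons (computable from published summary tables alone),
  quadrant-share tables.
* **Age regression**: least-squares fits of `y = a·ln(Age) + b` (BTV) and
  `y = a/Age + b` (MGV, PBD) with residual standard error
  `RSE = sqrt(SSE/(n − 2))`, including count-weighted fits on grouped
  means and an exact grouped-statistics reconstruction of the SSE:
  `SSE = Σ_g [(n_g − 1)·SD_g² + n_g·(mean_g − ŷ(age_g))²]`.
* **Synthetic phantoms**: a pendant-breast CT generator with analytic
  partial-volume ground truth (exact per-voxel glandular fraction), and a
  tabular cohort simulator — so every stage is testable without patient
  data.

## Worked example

Generate the default noiseless study phantom (200³ voxels, 0.3 mm,
true density ≈ 14%), segment it, and measure the composition:

```r
library(bctdensity)

spec <- phantomSpec(noiseSD = 0)      # default 200^3 study phantom
ph   <- generatePhantom(spec)
ph$truth
#> PhantomTruth: BTV 24.58 cm^3, MGV 3.151 cm^3, PBD 12.82%, nipple (154, 100, 100)

labels    <- segmentAll(ph$volume)
partition <- assignQuadrants(labels)
comp      <- composeFeatures(ph$volume, labels, partition)
comp
#> BreastComposition (BTV/MGV in cm^3, PBD in %):
#>  region btv_cm3 mgv_cm3 pbd_hu_pct pbd_vol_pct share_btv_pct share_mgv_pct pbd_ratio_pct
#>  Entire   24.71    3.27      13.52       13.25            NA            NA            NA
#>     UOQ    6.18    0.94      15.42       15.21            25         28.71        114.04
#>     UIQ    6.18    0.15       2.94        2.36            25          4.45         21.75
#>     LOQ    6.18    1.11      18.06       17.90            25         33.79        133.55
#>     LIQ    6.18    1.08      17.67       17.51            25         33.05        130.65
```

The measured whole-breast BTV (24.71 cm³), MGV (3.27 cm³) and HU-based
PBD (13.5%) recover the phantom's exact truth (24.58 cm³, 3.15 cm³,
12.8%) to within 0.5%, 4% and 0.7 density points; quadrant values sum
exactly to the whole-breast values, and the uneven gland shares reflect
where the generator placed the glandular components.

Fitting the logarithmic BTV–age model to the packaged reference
age-group table (seven groups, count-weighted) and reconstructing its
residual standard error from the grouped statistics:

```r
ref <- referenceAgeGroupStats()
fit <- fitAgeModel(ref$age_mean, ref$btv_mean, "log", weights = ref$n)
fit
#> RegressionFit (log): y = a * ln(Age) + b, weighted
#>   a = 285.2 (se 63.4, p 0.00642)
#>   b = -533.9 (se 256, p 0.091)
#>   RSE = 288.5 on 5 degrees of freedom (n = 7)

rseFromGroupStats(ref$age_mean, ref$n, ref$btv_mean, ref$btv_sd, fit)
#> [1] 384.812
```

The fitted curve says an average breast gains tissue volume
logarithmically with age (285 cm³ per ln-year), while the grouped
reconstruction puts the residual scatter of individual breasts about the
curve at ≈ 385 cm³ — the within-group variability dominates the
lack-of-fit of the group means.

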