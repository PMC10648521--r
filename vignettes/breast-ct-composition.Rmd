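---
title: "Quantifying breast composition from pendant-breast CT: methods and design notes"
author: "bctdensity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying breast composition from pendant-breast CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bctdensity)
```

## The problem

Dedicated spiral breast CT (BCT) images the pendant breast of a prone
patient in true 3D at roughly (300 µm)³ voxels, with Hounsfield units (HU)
that separate adipose tissue (≈ −100 HU) from fibroglandular tissue
(≈ +40 HU). That separation makes three quantitative composition features
accessible per breast:

* **BTV** (breast tissue volume, cm³) — the volume of all adipose plus
  glandular tissue;
* **MGV** (mammary gland volume, cm³) — the volume of the glandular
  tissue;
* **PBD** (percent breast density, %) — the glandular fraction of the
  breast tissue.

Because breast density is an established independent risk factor for
breast cancer, and because mammographic dose models conventionally assume
a much denser breast (50%) than volumetric measurements support, these
features — per whole breast and per clinical quadrant, and their
dependence on age — are of direct clinical interest. `bctdensity`
implements the full measurement chain: tissue segmentation, quadrant
localization from the nipple landmark, feature extraction, age-group
statistics, and the two age-regression families used to summarize the
trends (logarithmic for BTV, multiplicative inverse for MGV and PBD),
together with a synthetic phantom generator that provides exact ground
truth in place of patient scans, which are not publicly available.

## The synthetic phantom

`generatePhantom()` builds a pendant-breast acquisition from geometric
primitives on a configurable grid (default 200³ voxels of (0.3 mm)³ — a
60 mm field of view holding a deliberately scaled-down breast so that a
whole phantom generates and segments in well under a minute on one CPU):

* a **pectoral slab** (muscle, +45 HU) filling the chest end of the scan,
  cut by the image boundary at slice 1;
* a **half-ellipsoidal breast** (adipose, −100 HU) attached to the slab,
  hanging toward the high-index slices — the package's fixed axis
  convention is that axis 1 runs chest wall → nipple, so "most posterior
  slice" always means the highest tissue-bearing slice index;
* a **skin shell** (+30 HU) of constant thickness (default 1.5 mm) over
  the whole body surface except the chest cut, with a **nipple** bump at
  the breast apex that protrudes by less than the skin thickness and is
  therefore entirely skin, as nipples are conventionally classified;
* **glandular inclusions** (+40 HU): random ellipsoids whose centers are
  drawn per quadrant with configurable weights (default 34 : 21 : 26 : 18
  for UOQ : UIQ : LOQ : LIQ, mirroring the heterogeneous quadrant gland
  shares observed in screening cohorts) and rescaled by a common factor
  until the true gland volume is within 5% of the requested target
  (default 3.2 cm³, about 14% density — typical of the screening-age
  breast);
* optional **ribs** (+700 HU) inside the slab and an optional
  **skin-fold flap** of the thoracic wall attached to the slab rim but
  separated from the breast by an air gap;
* additive Gaussian HU noise (default SD 20 HU, a plausible magnitude for
  photon-counting BCT at this voxel size).

Every boundary voxel carries a partial-volume HU computed from an
approximate signed distance to the primitive surfaces (linear ramp one
voxel wide), so the phantom has an analytically defined per-voxel
glandular fraction. True BTV/MGV/PBD — whole-breast and per quadrant —
derive from that fraction, which makes the HU-based density estimator
testable at sub-voxel precision. A test verifies that the voxelized
volume of a 6 × 5 × 4 mm ellipsoid matches the closed form within 2% at
0.3 mm voxels and that the error at least halves at 0.15 mm.

Two geometric subtleties matter and are easy to get wrong:

* the union of primitives is represented by the pointwise minimum of their
  signed distances. A half-ellipsoid capped at the attachment plane would
  introduce a spurious *internal* surface there, making the analytic skin
  shell disagree with a true morphological erosion. The full ellipsoid
  therefore enters the union (its lower half is inside the slab), and the
  breast/chest split is made explicitly at the attachment plane;
* gland components are placed with their whole extent (plus rescaling
  headroom) clear of both the skin shell and the chest-wall junction, so
  that ground truth never straddles a class boundary. The phantom
  consequently does not emulate glandular tissue abutting the chest wall;
  this is a deliberate simplification that keeps truth unambiguous.

What the phantom does **not** emulate: reconstruction artifacts, beam
hardening, scatter, anatomical texture (Cooper's ligaments, ducts),
lesions or calcifications (such cases are excluded from composition
studies anyway), or full-size breasts. Passing recovery tests therefore
demonstrates correctness of the measurement chain under controlled
partial-volume and noise conditions, not clinical segmentation accuracy
on patient data.

`simulateCohort()` is the tabular counterpart: it draws integer patient
ages (40–74 years, uniformly or with per-5-year-bin counts), evaluates
the three published mean curves (`referenceAgeModels()`: BTV = 290 ln(Age)
− 554 cm³, MGV = 4885/Age − 26 cm³, PBD = 1237/Age − 8.4%) and adds
Gaussian noise with SDs defaulting to those models' residual standard
errors (386 cm³, 67 cm³, 13%). By default values are then clamped to
their physical ranges (BTV ≥ 0, 0 ≤ MGV ≤ BTV, 0 ≤ PBD ≤ 100). The clamp
makes records physically valid but necessarily biases means near the
boundaries (Gaussian noise of SD 67 cm³ around means of 40–90 cm³ has
appreciable mass below zero); closed-loop estimator-recovery tests
therefore simulate with `truncate = FALSE`, because unbiased coefficient
recovery is a property of the Gaussian-error model that the least-squares
regression assumes, not of a censored variant of it. This is the
package's own resolution of a genuine tension between physical validity
and estimator calibration, and both modes are exposed.

## Segmentation

`segmentAll()` classifies every voxel into air, adipose, gland, skin,
pectoralis, rib, or skin-fold:

1. **Body**: HU above `airThreshold` (−500), largest connected component,
   cavities filled.
2. **Skin**: the body minus its morphological erosion by a ball of radius
   `skinThickness` (1.5 mm), computed via an exact Euclidean distance
   transform (Felzenszwalb/Huttenlocher, implemented in C++). Space
   beyond the image border counts as foreground, so the chest cut face is
   not mislabeled as skin. Thickness is specified in millimetres and
   converted through the distance transform, making the rule
   resolution independent.
3. **Chest structures**, searched only within `chestExtent` (15%) of the
   slices adjacent to the chest end: ribs are voxels at or above
   `ribThreshold` (150 HU); the pectoralis is the connected component of
   soft-tissue-dense voxels (HU ≥ `pectoralisThreshold`, default 0)
   touching the chest face. The 0 HU default sits above everything a
   skin-to-fat partial-volume blend can produce (at most ≈ +30 HU skin
   mixed into −100 HU fat at sub-half occupancy stays below −35 HU), so
   boundary voxels cannot bridge breast tissue to the chest wall, yet it
   is 2+ noise SDs below muscle. Skin folds are the tissue components
   left disconnected from the main breast component after muscle and rib
   removal.
4. **Gland**, by adaptive region growing on the remaining breast
   interior. The fat and gland reference HU means are estimated from the
   interior itself — an Otsu split of the HU histogram (256 bins, ties
   toward the lower threshold), then the median of each side. Every
   interior voxel gets a glandular fraction
   `g = clamp((HU − muFat)/(muGland − muFat), 0, 1)`. Voxels with
   `g ≥ seedFraction` (0.8) seed the region; each sweep accepts
   26-connected neighbours with
   `g ≥ max(floorFraction, alpha · (1 − D))`, where `D` — the running
   average breast density — is the mean glandular fraction over the
   region grown so far, recomputed after each exhaustive sweep
   (`floorFraction` 0.25, `alpha` 0.5). Growth stops when a sweep adds
   nothing and `D` moves less than `tol` (10⁻⁴), or after
   `maxIterations` (50) sweeps. The acceptance threshold thus *relaxes*
   in dense breasts (large `D`) and tightens in fatty ones, while the
   floor keeps it from descending into pure fat. The procedure is
   deterministic, and the per-sweep `D` trace is returned for
   diagnostics.

If the interior HU histogram shows no glandular population (mode
separation below `minModeSeparation`, 60 HU — well under the ≈ 140 HU
fat-to-gland distance but above what noise or residual partial-volume
blends produce), the gland mask is empty with a warning rather than an
error: an all-adipose breast is a legitimate input.

On noiseless inputs whose gland cores keep `D ≥ 1 − floorFraction/alpha`,
the grown region provably equals the plain threshold `g ≥ floorFraction`
restricted to components containing a seed; the tests exploit this as an
exhaustive independent oracle on small grids. A parameter sweep also
checks monotonicity: raising the floor never grows the region.

Under the default 20 HU noise the voxel-count MGV inflates noticeably
(noise lifts a few percent of fat voxels above the acceptance threshold
along the region boundary) and the clamp in `g` biases the HU-based PBD
upward over pure-fat regions; the noiseless phantom is the calibration
reference, and real pipelines would denoise upstream. This sensitivity
is a property of the growing rule itself and is documented rather than
patched with smoothing, which would blur the partial-volume information
the density estimate relies on.

## Quadrants

The nipple is located as the centre of mass of the skin voxels in the
most posterior (highest-index) tissue slice, rounded to the nearest
voxel. Two perpendicular planes through the nipple, parallel to the image
rows and columns, split the breast-tissue voxels into UOQ/UIQ/LOQ/LIQ.
Rows with indices at or below the nipple row are "upper"; the outer
(lateral) column side follows laterality under the documented convention
that image columns run patient-right → patient-left (right breast: lower
columns are outer), overridable via `outerSide` for other acquisition
conventions. Voxels exactly on the row plane count as upper and on the
column plane as outer — a deterministic tie rule affecting at most a
one-voxel sheet. No central/retroareolar region is modelled, matching
the four-quadrant scheme. Mirror and rotation symmetry tests pin the
orientation logic down exactly.

## Features

BTV and MGV are voxel counts times voxel volume; whole-breast values are
computed as the sum of the four quadrant values, so additivity is exact
to the last bit. PBD is reported in two variants, because "the percent
ratio between MGV and BTV" and "calculated from the HU values" differ
under partial volume:

* `pbd_hu_pct` (primary): 100 × the mean glandular fraction `g` over the
  region's tissue voxels, with reference means `muFat`/`muGland` taken
  from the mean HU of 2-voxel-eroded adipose and gland cores (erosion
  avoids partial-volume contamination; fixed values can be supplied
  instead, e.g. from a scanner calibration);
* `pbd_vol_pct` (secondary): 100 × MGV/BTV from the classified counts.

The two coincide exactly on binary images (a tested identity). Quadrant
shares (percent of whole-breast BTV and MGV) and the quadrant-to-whole
PBD ratio complete the `BreastComposition` table; shares are reported as
missing when the whole-breast denominator is zero, never silently
dropped.

## Cohort statistics and regression

`summarizeByAge()` bins per-breast records into the seven 5-year groups
(40–44 … 70–74) and reports counts, means and sample SDs (n − 1); records
outside 40–74 are excluded with a logged count. The analysis unit is the
breast, not the woman, following the study design this reproduces; no
within-patient correlation adjustment is made. Group comparisons use the
pooled-variance Student t-test (two-sided), implemented in closed form
from summary statistics so that published tables can be tested directly;
the raw-data path is a thin wrapper over the same formula, and
`stats::t.test` serves as the independent oracle in the tests (agreement
to 10⁻¹⁰, and a 10,000-replicate null simulation confirms the nominal 5%
type-I error). A Welch variant is available behind a flag.

`fitAgeModel()` fits `y = a·ln(Age) + b` or `y = a/Age + b` by
(optionally weighted) least squares via `stats::lm` on the transformed
regressor, with standard errors and two-sided p-values from linear-model
theory at n − 2 degrees of freedom. Whether the original models were fit
to individual records or to the seven sub-cohort means is ambiguous in
the source description (the predictor is described as the average age of
each sub-cohort); both modes are supported, and the reproduction targets
use the count-weighted group-mean fit, which with integer weights is
identical to an unweighted fit on row-replicated data (a tested
identity) and approximates the individual-level fit up to within-group
age variation (±1–2 years here).

The residual standard error is `sqrt(SSE/(n − 2))`. When only grouped
summaries are available, `rseFromGroupStats()` reconstructs the SSE
exactly (for group-constant ages) from
`SSE = Σ_g [(n_g − 1)·SD_g² + n_g·(mean_g − ŷ(age_g))²]` — the
within-group variance plus the lack-of-fit of the group means. Applied to
the packaged reference table (`referenceAgeGroupStats()`: seven age
groups, 1033 examinations) this reconstruction is what
`scripts/acceptance.R` recomputes, along with the count-weighted
coefficients themselves. The packaged table stores the published numbers
exactly as printed; its bin counts total 1033 while the accompanying text
reports 1027 examinations — the discrepancy is preserved and surfaced in
the accessor's documentation, not resolved.

## Numerical and design choices at a glance

* Distance transform: exact squared Euclidean, anisotropic spacing
  supported; out-of-image space is foreground (no erosion at the chest
  cut).
* Connectivity: 26-connected for region growing and component analysis of
  tissue structures, 6-connected for the body mask and hole filling.
* Otsu split: 256 fixed-width bins; ties broken toward the lower
  threshold (conservative gland class); medians as robust population
  means.
* Degenerate inputs fail fast with explicit messages: all-air volumes,
  skin thickness consuming the whole body, constant-age designs,
  non-positive ages, gland targets beyond the phantom interior.
* All randomness (phantom placement, noise, cohort draws) flows from the
  seed stored in the spec objects; generation restores the caller's RNG
  state. Same seed ⇒ bit-identical output (tested).
* Problem sizes used by the shipped tests: 48³–128³ phantoms for unit
  tests, one 200³ noiseless phantom for the end-to-end recovery checks,
  200 replicates of n = 1033 cohorts for regression recovery — sizes
  chosen so the whole suite exercises study-scale conditions while
  remaining comfortably reproducible on a laptop.

## Known limitations

* The concrete adaptive-growing constants (seed 0.8, floor 0.25, α 0.5,
  convergence on `D`) are this package's own realization of the
  published mechanism; the original algorithm's exact acceptance formula
  is not public, so fidelity beyond the stated mechanism cannot be
  verified.
* HU reference values are literature-typical, not scanner calibrations.
* The phantom's geometry is simplified and scaled down; accuracy numbers
  from phantom recovery do not transfer to patient data.
* The segmentation is intentionally free of denoising and machine
  learning; noisy inputs inflate MGV and HU-based PBD as described
  above.
* Published coefficient uncertainties for the reference models cannot be
  reproduced from grouped summaries alone and are not targeted.
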