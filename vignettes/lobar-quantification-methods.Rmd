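---
title: "Methods: lobar V/Q quantification on digital thorax phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lobar V/Q quantification on digital thorax phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lobarquant)
```

## The problem

Regional lung ventilation and perfusion (V/Q) guide decisions such as lung
resection planning and endobronchial valve placement. Two quantification
approaches dominate clinical practice:

* **Planar equal-thirds template.** Anterior and posterior planar
  scintigraphy images are acquired (or, as here, synthesized by attenuated
  forward projection of the SPECT volume). After the lungs are delineated,
  each lung's cranio-caudal extent is split into three equally sized
  rectangular regions and each third is read as the corresponding lobe.
  Because the left lung has only two lobes, the left middle-third counts are
  halved and added to the left superior and inferior counts. The method is
  fast but the thirds have nothing to do with the true fissure positions.
* **3D lobar counting on SPECT/CT.** Lobes are segmented on the CT volume
  (manually or by an automated tool), the label map is transferred to the
  SPECT counts, and each lobe's counts are summed directly.

This package implements both methods end-to-end on *synthetic digital thorax
phantoms* whose ground-truth lobar activity fractions are known by
construction, so the systematic bias of the planar template and the
interobserver behavior of each method can be measured exactly — something
patient data never allows.

## The phantom

The thorax is a soft-tissue ellipsoid (default half-axes 150 x 105 x 180 mm)
containing two ellipsoidal lungs. Patient axes are fixed: x = left(+),
y = anterior(+), z = superior(+). Rasterization is analytic at any requested
grid — a voxel belongs to a structure when its center lies inside the
analytic surface — so there are no label-resampling artifacts and the same
spec can be rendered at 3.3 mm and 1.1 mm with sub-1.5-percentage-point
agreement in lobar volume shares (asserted by test).

**Fissures are planes.** The oblique fissures are tilted in the sagittal
plane (default 38 degrees, raising the plane posteriorly so the inferior
lobes reach higher dorsally, as in normal anatomy); the right horizontal
fissure bounding the middle lobe is near-axial. Planes are the simplest
geometry that exhibits the property the study turns on: the real lobar
extents differ strongly from equal axial thirds. Curved fissure surfaces
would change the numbers, not the direction, of the template bias.

**Default geometry.** Fissure heights (fractions of the apex-base extent)
default to `h_right_oblique = 0.45`, `h_right_horizontal = 0.56`,
`h_left_oblique = 0.46`. These were calibrated once, against the right-lung
lobar shares a 3D SPECT method reports in a typical clinical population
(approximately 39/18/43 percent RUL/RML/RLL of the right lung, and 56/44
LUL/LLL on the left), so that the planar-bias experiments operate in a
realistic regime. They are not revisited per experiment.

**Tissue values.** HU defaults: air -1000, lung parenchyma -800,
emphysematous parenchyma -950, soft tissue +40. Activity is specified per
lobe in arbitrary units per voxel; only relative distributions are
meaningful, so absolute calibration (MBq) is deliberately out of scope.

**Pathology decorations.** `apply_emphysema()` multiplies lobe activity by a
factor in [0, 1] and lowers HU; `insert_hotspot()` multiplies activity
inside a sphere (hotspot counts are *not* subtracted downstream — they hit
all methods identically); `apply_lobectomy()` removes a lobe, replacing it
with soft tissue and zero activity.

**Population variability.** `random_phantom_spec()` draws half-axes within
+/-7% (thorax +/-5%), lung centers within +/-5 mm, fissure heights within
+/-0.04, tilts within +/-4 degrees, and per-lobe specific activities
log-normally (sdlog 0.15) per tracer. These ranges are the package's own
choice of a plausible adult population; no cohort statistics were available
to fit them to.

## The imaging model

The full acquisition chain (projections, collimator response, scatter
windows, OSEM reconstruction) is *not* simulated. The analysis consumes
reconstructed images, so the package models their product directly:

1. the activity volume is scaled to a total count level (default 5e6 counts,
   a plausible clinical figure for a reconstructed lung SPECT; the true
   count level of clinical reconstructions is rarely reported, so this is an
   exposed configuration value, not an estimate);
2. an isotropic Gaussian point-spread function of 5 mm FWHM is applied
   (sigma = FWHM/2.3548, truncated at 4 sigma). The 1D smoothing matrices
   are *column*-normalized, i.e. each source voxel distributes exactly its
   own counts over in-bounds destinations, so totals are conserved to
   machine precision even at the volume edges;
3. with noise on, every voxel becomes a Poisson draw with the blurred value
   as its mean. Applying Poisson noise after the blur is not physically
   exact (real noise enters in projection space), but it preserves count
   statistics at the level the quantification sees, which is what matters
   for the comparisons made here.

The attenuation map uses the standard bilinear HU-to-mu conversion at the
140 keV photon energy of 99mTc: `mu = mu_water (1 + HU/1000)` below 0 HU
(floored at 0), slope halved above 0 HU (`bone_slope = 0.5`). The water
anchor is `mu_water = 0.0151` per mm. Both constants are configurable; no
single published formula is canonical.

## Planar reprojection

`project_planar()` synthesizes anterior (0 degrees) and posterior
(180 degrees) views by parallel-beam ray sums along the anteroposterior
axis with exponential attenuation of the mu integral:

    pixel(x, z) = sum_y counts(x, y, z) * exp(-dy * (sum of mu between the
                  voxel and the detector-side boundary + mu_self / 2))

The half-voxel self-attenuation term is a declared convention (second-order
accurate for an emitter at the voxel center) chosen so that closed-form
tests are exact: a point source at depth d in a uniform slab projects to
`A exp(-mu d)`, and the anterior and posterior factors of any voxel multiply
to `exp(-mu D)` for a slab of thickness D. That identity is why the default
view combination is the **geometric mean**: `sqrt(A x P)` is independent of
source depth in a uniform attenuator. The combination rule used by clinical
workstations varies and is rarely documented, so the mode is explicit in
every report (`arithmetic_mean`, `anterior_only`, `posterior_only` are also
available). Only the two 0/180-degree views are implemented; arbitrary-angle
reprojection is a non-goal.

## Planar quantification choices

* Lung delineation defaults to the projection of the true lobe labels. This
  deliberately isolates the *template-geometry* bias — the subject of the
  study — from delineation error. A threshold-based delineation
  (`delineate_lungs_planar()`: pixels at or above 10% of the 99.5th
  percentile, two largest components) is provided for realism experiments.
* The equal thirds split the bounding-box z-extent at `round(H/3)` and
  `round(2H/3)` with round-half-away-from-zero, so band heights differ by at
  most one pixel; bands are intersected with the lung delineation (a whole
  rectangle mode exists as a switch).
* Background counts are measured in a rectangle placed lateral to each lung,
  outside the body silhouette, and subtracted as mean-background-per-pixel
  times ROI size; negative corrected counts are clipped to zero and flagged.

## Observer simulation

Observer disagreement is modeled **only through geometry**: in both manual
workflows the counts are fixed and only delineations differ between readers.

* *Planar* observers jitter each bounding-box edge by rounded
  Normal(0, sigma_px = 2 px) draws and re-place the background ROI with a
  jittered gap.
* *Manual 3D* observers displace the fissure-plane heights by
  Normal(0, sigma) draws — sigma_oblique = 3 mm, sigma_horizontal = 6 mm
  (the horizontal fissure is the hardest to see on CT, hence the larger SD)
  — and tilt each plane by Normal(0, 2 degrees). Only internal fissures
  move; lung outer boundaries are fixed. A direct consequence: whole-lung
  totals are mathematically invariant for the manual method, so its
  whole-lung RSD is exactly zero under this model, unlike for real readers
  who also redraw the lung outline.
* *Automated 3D* is deterministic (zero jitter): an idealization of an
  auto-segmentation tool whose residual manual-check variability is small.

The jitter SDs are tuning constants calibrated once so that default runs
land in clinically reported interobserver regimes (planar RSDs of roughly
5-25%, manual RML RSD of order 10-20%, automated 0%); they are not estimates
fitted to any dataset. Interobserver variability is summarized as the
relative standard deviation, `100 * sd / mean` (n-1 denominator), per
region, averaged over phantoms (default: 10 phantoms, 3 observers, matching
a typical interobserver sub-study). Seeding is hierarchical — observer k of
phantom j uses substream (seed, j, k) — so studies are reproducible and
observers independent.

## Statistics

Methods are compared per region (five lobes plus both whole lungs) and per
tracer with **Welch's heteroscedastic one-way ANOVA** (implemented from the
standard formulas and cross-checked against an independent reference
implementation to 1e-10 on random inputs; for k = 2 it reduces to the
squared Welch t-test). Results are reported as mean, 95% t confidence
interval, and min-max range per method, with the Welch F*, degrees of
freedom, and raw p-value at alpha = 0.05. No multiple-testing correction is
applied across the 7 regions x 2 tracers — the report mirrors the raw
per-region convention of clinical validation tables, and says so in its
footer. Omnibus ANOVA only: post-hoc pairwise contrasts are out of scope.

## Numerical and degenerate-input choices

* Rasterization is deterministic given (spec, grid); the spec seed only
  drives stochastic decorations (hotspot center jitter).
* Degenerate geometry fails loudly: a lung poking out of the thorax, a lung
  crossing the body midline, or a lobe empty at the requested resolution
  raises an error naming the lobe.
* A fissure perturbation that empties a lobe is resampled up to 10 times,
  then errors.
* Gaussian kernel truncation at 4 sigma with per-position renormalization
  bounds the conservation error below 1e-6 (in practice, machine epsilon).
* Background-subtraction clipping events and absent lobes (lobectomy) are
  carried as flags on the distribution objects rather than silently eaten.
* Ties in the equal-thirds rounding and in majority-label block resampling
  are broken by declared rules (round half away from zero; smallest label
  code) so tests can be exact.

## Problem sizes

The package defaults reproduce the full study geometry: 128^3 voxels at
3.3 mm, 5e6 counts, 43 phantoms for the method comparison, 10 phantoms x 3
observers for the interobserver arm. The test suite exercises geometric and
statistical properties on a coarser 64^3 / 6.6 mm grid covering the same
field of view — the properties checked are resolution-independent — and
runs the acceptance-level checks (ground-truth recovery, planar bias
direction, observer-variability ordering, reproducibility) at the full
default resolution with 20-phantom and 20-replicate simulations.

## What passing tests do and do not show

The phantoms capture the features the comparison turns on: lobar anatomy
with a small anterior middle lobe, CT-consistent attenuation, system blur,
and counting noise. They do *not* capture airways and vessels, respiratory
motion, scatter, reconstruction artifacts, non-ellipsoidal chest walls, or
reader behavior beyond geometric jitter. Passing tests therefore establish
that the *methods* behave as described on anatomy of known truth — e.g.
that the equal-thirds template structurally inflates the right middle lobe
— not that any particular clinical percentage will be reproduced in
patients.
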