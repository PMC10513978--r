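# lobarquant

Lobar ventilation/perfusion (V/Q) quantification on digital thorax phantoms:
a simulation laboratory for comparing the clinical **planar equal-thirds
template** against **3D SPECT lobar counting**, with known ground truth.

## The problem

Regional V/Q estimates guide lung resection and endobronchial valve
decisions. The common clinical method projects the tracer distribution onto
anterior/posterior planar images and splits each lung's cranio-caudal extent
into three equally sized rectangular ROIs, reading each third as a lobe
(the left lung has no middle lobe, so its middle-third counts are halved and
redistributed). Those thirds ignore the true fissure positions, so the
method is systematically biased for the right lung lobes — especially the
small, anterior right middle lobe (RML). 3D SPECT/CT lobar counting avoids
the bias but needs a lobe segmentation, whose manual form is slow and
reader-dependent.

With patient data the true lobar fractions are unknowable, so `lobarquant`
builds digital thorax phantoms where they are known by construction:

* **phantom** — ellipsoidal thorax and lungs, planar fissures, per-lobe
  activity for ventilation and perfusion, HU volume; optional emphysema,
  hotspots, lobectomy; analytic rasterization at any grid.
* **imaging** — reconstructed-SPECT surrogate (activity scaled to a count
  level, 5 mm FWHM Gaussian PSF, Poisson noise) and bilinear HU-to-mu
  conversion at 140 keV (`mu = mu_water (1 + HU/1000)` below 0 HU, slope
  0.5 above).
* **projection** — planar scintigraphy synthesized by attenuated forward
  projection: `pixel(x,z) = sum_y counts * exp(-integral of mu)` toward the
  detector, with a half-voxel self-attenuation convention.
* **quantify** — the six-ROI equal-thirds template (background subtraction,
  geometric-mean view combination, left middle redistribution) and 3D lobar
  counting on a label map.
* **observers** — simulated readers: jittered planar bounding boxes,
  displaced/tilted fissure planes (manual 3D), deterministic automated 3D;
  interobserver relative standard deviations (RSD = 100 * sd/mean).
* **stats** — Welch's heteroscedastic one-way ANOVA across methods with 95%
  t confidence intervals and ranges, per region and tracer; full pipeline
  driver with byte-reproducible reports.

## Worked example

```r
library(lobarquant)

ph <- build_phantom(phantom_spec())           # 128^3 voxels at 3.3 mm
true_lobar_fractions(ph, "V")
#> <lobar_distribution> tracer=V method=truth
#>        RUL        RML        RLL        LUL        LLL right_lung  left_lung
#>      21.18       9.69      23.54      25.25      20.33      54.41      45.59

spect <- simulate_spect(ph, tracer = "V", seed = 7)   # 5e6 counts, 5 mm PSF
mu    <- mu_map_from_phantom(ph)
views <- project_planar_views(spect, mu)
rois  <- build_planar_rois(labels = ph$labels, hu = ph$hu)

quantify_planar(views$anterior, views$posterior, rois)
#> <lobar_distribution> tracer=V method=planar
#>        RUL        RML        RLL        LUL        LLL right_lung  left_lung
#>      13.81      27.56      13.80      22.67      22.15      55.17      44.83

quantify_lobar(spect, ph$labels)
#> <lobar_distribution> tracer=V method=lobar_3d
#>        RUL        RML        RLL        LUL        LLL right_lung  left_lung
#>      21.18       9.76      23.51      25.23      20.31      54.45      45.55
```

The three blocks are the point of the package in miniature: the truth puts
9.7% of ventilation in the RML; the planar template reads 27.6% there (and
correspondingly too little in the superior and inferior right lobes), while
3D lobar counting on the same noisy SPECT volume recovers every region to
within 0.1 percentage points. Whole-lung totals agree across all methods to
within about one point — the bias is a right-lobe geometry effect, not a
counting effect.

A full study (43 phantoms, both tracers, Welch ANOVA tables, 10-phantom
3-observer interobserver arm) runs with:

```r
report <- run_pipeline(study_config(seed = 1), out_dir = "study_out")
print(report)
```

A thin command-line front end with subcommands (`phantom`, `simulate`,
`project`, `quantify`, `observer-study`, `run-all`) lives at
`inst/cli/lobarquant.R`.

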