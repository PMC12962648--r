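# alpsfw

Diffusion-MRI biomarkers of neurofluid dynamics — the DTI-ALPS index and the
free-water (FW) volume fraction — carried through to prognostic survival
stratification in multi-site glioma cohorts, with a synthetic-data module
that makes every stage verifiable at desk scale.

## The problem

Glioblastoma appears to disturb the glymphatic system — the brain-wide
perivascular pathway that exchanges CSF and interstitial fluid — not only
around the tumor but also in the contralateral hemisphere. Two diffusion-MRI
surrogates capture this:

* **DTI-ALPS index.** At the level of the lateral-ventricle bodies,
  projection fibers run superoinferior (z) and association fibers
  anteroposterior (y), while perivascular spaces run right–left (x),
  perpendicular to both. With `Dxx`, `Dyy`, `Dzz` the diagonal entries of
  the fitted diffusion tensor in image axes, averaged over 4-mm spherical
  ROIs in each fiber system,

  ```
  ALPS = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)
  ```

  A ratio near 1 means no preferential diffusion along the perivascular
  axis; lower values suggest reduced perivascular flow.

* **FW fraction.** A two-compartment (bi-tensor) model
  `S = S0 [(1 − f) exp(−b gᵀD_t g) + f exp(−b d_iso)]`, with
  `d_iso = 3.0e-3 mm²/s`, separates an isotropic free-water compartment `f`
  from the tissue tensor `D_t`. Elevated mean FW in contralateral
  normal-appearing white matter (cNAWM) indicates interstitial fluid stasis.

The package implements the full analysis chain: weighted-least-squares
tensor fitting, ALPS ROI placement and tumor-overlap categorization,
regularized single-shell bi-tensor FW estimation, ComBat location/scale
harmonization across acquisition sites (preserving age and sex effects),
Kaplan–Meier / log-rank / Cox survival analysis, optimal-cutpoint scanning
with external-cohort validation, and joint ALPS×FW three-group
stratification. A phantom and cohort simulator provides ground truth for
every stage.

## Worked example

```r
library(alpsfw)

# a 32^3 phantom with fibers, a planted perivascular Dxx elevation (+50%),
# a left-sided tumor not touching the ROIs, and a simulated acquisition
shape <- c(32, 32, 32)
ph   <- make_phantom(shape, region_spec = default_region_spec(shape, dxx_elevation = 0.5))
rois <- make_rois(ph)                       # 4-mm spheres, both hemispheres
seg  <- make_tumor_labels(ph, "left", "none", rois = rois)
dwi  <- simulate_dwi(ph, scheme_upenn_like(31), snr = 40, seed = 3)

rec <- run_subject(dwi, seg, rois, cnawm = cnawm_mask(ph, "left"),
                   subject_id = "P1")
rec[, c("roi_category_ipsi", "alps_cnawm", "alps_inawm", "fw_cnawm")]
#> # A tibble: 1 x 4
#>   roi_category_ipsi alps_cnawm alps_inawm fw_cnawm
#>   <chr>                  <dbl>      <dbl>    <dbl>
#> 1 iNAWM                   1.50       1.50   0.0853
```

The recovered ALPS of 1.50 matches the phantom's analytic value
(`0.45e-3 / 0.30e-3`); both hemispheres are tumor-free at the ROIs, so the
ipsilateral one is iNAWM and the contralateral cNAWM; FW is low because the
phantom contains no free water and the fibers are strongly anisotropic.

A cohort-level run — harmonization, ANOVA over ROI categories, median
splits, Cox models, cutpoint discovery and validation:

```r
coh <- simulate_cohort(cohort_spec(
  n_per_site  = c(UPENN = 300, UCSF = 270),
  site_effects = list(UPENN = list(shift = 0, scale = 1),
                      UCSF  = list(shift = 0.1, scale = 1.2))
), seed = 5)
run <- run_cohort(coh)
run
#> <cohort_run> 518 subjects after filtering (discovery UPENN, validation UCSF)
#>   thresholds: ALPS 1.44, FW 0.319
#>   validation log-rank p: ALPS 0.0005996, FW 0.00816
```

The simulator plants per-SD log hazard ratios of −0.3 (ALPS) and +0.3 (FW);
the discovery scan finds a threshold near the biomarker median and the
fixed threshold transfers to the validation site with a significant
log-rank test. `tidy()`, `glance()` and `autoplot()` methods are available
for the fitted objects (`cox_fit`, `cutpoint_scan`, `km_curve`,
`combat_model`, `joint_strata`).

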