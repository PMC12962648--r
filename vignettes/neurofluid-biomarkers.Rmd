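---
title: "Neurofluid biomarkers: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neurofluid biomarkers: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alpsfw)
```

This vignette is the package's account of its science: the models it fits,
the parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical and design choices made where the design was
genuinely open.

## The signal model and tensor fit

A diffusion-weighted acquisition measures, per voxel and gradient volume,

$$S(b, g) = S_0\left[(1-f)\,e^{-b\,g^\top D_t\, g} + f\,e^{-b\,d_{iso}}\right],$$

where $D_t$ is the tissue diffusion tensor (mm²/s), $f$ the free-water
volume fraction and $d_{iso} = 3.0\times10^{-3}$ mm²/s the diffusivity of
free water at body temperature. The single-tensor stage (`fit_tensor()`)
sets $f = 0$ and solves the log-linearized system
$\ln S = \ln S_0 - b\,g^\top D g$ by two-pass weighted least squares: an
ordinary LS pass, then a WLS pass with weights equal to the squared
predicted signals. This is the standard compromise between the bias of
plain log-linear fitting and the cost of full nonlinear estimation; on
noise-free data it is algebraically exact (the test suite verifies
recovery at $10^{-9}$ relative error). Signals are floored at
$10^{-6} S_0$ before the logarithm; voxels with nonpositive baseline are
flagged `fit_ok = FALSE` rather than aborting a whole volume.

`tensor_metrics()` derives FA and MD from eigenvalues clamped at zero, but
reads `Dxx`, `Dyy`, `Dzz` from the *raw tensor diagonal in image axes*:
the ALPS index is defined on axis diffusivities, not eigenvalues, and
clamping the diagonal would bias ratios near isotropy.

## The ALPS index

With 4-mm spherical ROIs in the projection (z-oriented) and association
(y-oriented) fiber systems adjacent to the lateral-ventricle bodies,

$$\mathrm{ALPS} = \frac{\mathrm{mean}(D_{xx,proj},\, D_{xx,assoc})}
                       {\mathrm{mean}(D_{yy,proj},\, D_{zz,assoc})}.$$

Each hemisphere's index uses only its own ROI pair. ROI categories are
assigned against the tumor segmentation: the hemisphere opposite the tumor
is cNAWM; the ipsilateral pair is categorized by overlap with tumor labels,
one shared voxel sufficing, with priority necrosis > enhancing >
FLAIR-hyperintense and iNAWM when nothing overlaps. The priority order
mirrors the exclusion of necrosis-overlap measurements from group
comparisons and the implicit severity ordering of the compartments; no
published tie rule exists, so the choice is the package's own and is
pinned by tests. Necrosis- and tumor-overlap ALPS values are blanked from
survival columns; the subjects stay in the cohort for contralateral
analyses. Reference-subject selection (`select_reference()`) minimizes the
sum of squared differences to an FA template, with ties broken by lowest
subject id so the choice is reproducible.

Measurements with a nonpositive denominator are flagged invalid rather
than erroring, so one corrupt subject cannot stop a cohort run.

## Free-water estimation on a single shell

`fw_fit_bitensor()` estimates $f$ and $D_t$ by alternating minimization of

$$\sum_{v}\sum_{i}\left(S_{model} - S_{obs}\right)^2
  + \lambda \lVert \nabla f \rVert^2 .$$

Given $f$, the free-water signal is subtracted and the tissue tensor refit
by log-linear least squares on the corrected signal (vectorized over the
volume). Given the tensors, the model is *linear* in $f$, so the penalized
subproblem is an exact quadratic with a discrete-Laplacian coupling; it is
solved by Jacobi sweeps and projected onto $[f_{min}, f_{max}] =
[0.01, 0.99]$ after every sweep, which keeps both compartments
identifiable. The spatial penalty is a Tikhonov/Laplacian smoother — a
deliberately simpler regularizer than gradient-descent-on-manifold
schemes, with the same qualitative role and much easier-to-test behavior.
Signals are normalized per voxel so the default `reg_weight = 0.5` is
comparable across acquisitions.

Initialization (`fw_init()`) matches the direction-averaged attenuation
$\bar A$ at the shell against pure-tissue and pure-water predictions,

$$f_0 = \frac{e^{-b\lambda_t} - \bar A}{e^{-b\lambda_t} - e^{-b d_{iso}}},$$

with tissue prior $\lambda_t = 0.6\times10^{-3}$ mm²/s — a conventional
white-matter mean diffusivity. This is an explicit, deliberately simple
attenuation-matching scheme; its job is only to start the fit inside the
feasible region on the correct side.

**Single-shell caveat.** With one b-value the voxel-wise bi-tensor problem
is ill-posed: in a perfectly isotropic voxel any $f$ paired with a
compensating tissue diffusivity fits the data exactly. Anisotropy breaks
the degeneracy, and the spatial penalty propagates that information, so
what is recoverable — and what the tests and acceptance checks assert — is
the *regularized mean* of $f$ over a region (bias below 0.1, rank order
across planted levels preserved), not voxel-exact maps. Convergence is
declared per voxel when the $f$-update falls below `tol` (default
$10^{-3}$); a materially increasing loss for three consecutive iterations
marks the volume nonconverged. The loss may jitter at rounding scale near
the fixed point because the tissue step works in the log domain, so only
increases above 0.1% count as divergence.

## ComBat harmonization

Biomarkers from different acquisition sites carry location/scale batch
effects. For feature $v$, subject $j$, site $i$:

$$y_{ijv} = \alpha_v + X_j \beta_v + \gamma_{iv} + \delta_{iv}\,\varepsilon_{ijv}.$$

`combat_fit()` standardizes each feature by the covariate-adjusted grand
mean and pooled variance, estimates per-site location ($\hat\gamma$) and
scale ($\hat\delta$), and shrinks them across features with parametric
empirical Bayes (normal prior on locations, inverse-gamma on variances,
moment-matched, fixed-point iteration). Age and sex are covariates in the
standardization and are restored on adjustment, so biological structure
survives. The fit/apply split lets a model fitted on a pooled table be
applied to new rows; unseen sites are an error.

Design choices worth recording:

* **Feature set.** ALPS (cNAWM and ipsilateral) and FW are harmonized
  jointly, giving the EB priors at least three features to pool over. With
  a single feature the raw per-site estimates are used (`eb_used = FALSE`).
* **Batches.** Dataset = site (two batches); scanner-level sub-batches are
  not modeled.
* **Variance divisor.** Per-site scale estimates use the population
  ($1/n$) divisor — the same convention as the pooled variance — so that
  harmonizing already-harmonized data is an *exact* fixed point and
  identical pseudo-sites are untouched. Reference implementations that use
  the $n-1$ sample variance differ by an $O(1/n)$ factor; the test suite
  cross-checks against one such implementation at that tolerance.
* **Idempotence.** The pure location/scale adjustment is exactly
  idempotent. The covariate-preserving variant is an approximate fixed
  point only: the per-site scale correction rescales within-site covariate
  slopes, so a refit finds residual effects of order the scale correction
  times the slope. Both properties are tested at their respective
  tolerances.

## Survival analysis and cutpoint discovery

Kaplan–Meier, log-rank and Cox proportional-hazards fits delegate to the
`survival` package (product-limit with Greenwood variance; Efron tie
handling by default — more accurate than Breslow and identical without
ties, which the tests verify). Median survival is reported in months
(days / 30.44); when the survival curve sits exactly at 0.5 over an
interval the interval midpoint is reported (the estimator's usual
convention). Continuous Cox covariates are z-scored by default so hazard
ratios are per SD — the only plausible reporting scale for indices whose
natural range is a few tenths; per-unit fitting remains available via
`standardize = FALSE`.

`scan_cutpoints()` walks a regular grid (ALPS step 0.01, FW step 0.001)
across the observed range, dichotomizing at each threshold
(`value > threshold` is "high", the same convention as the median split
and `apply_threshold()`, ties going low). The optimum is the lowest
log-rank p, ties broken by the largest $|\log \mathrm{HR}|$, then by the
lowest threshold — fully deterministic. Two deliberate properties:

* **No multiplicity correction.** Minimum-p selection is anticonservative
  under the null; the package documents and *tests* the inflation rather
  than correcting it, because the procedure being reproduced applies none.
  External validation at a fixed threshold is the guard against it.
* **Group-size floor.** `min_group_frac = 0.1` by default prevents
  degenerate 1-vs-(n−1) splits; set it to 0 to scan the full range.

Joint stratification combines both markers at fixed thresholds:
favorable = high ALPS & low FW, adverse = low ALPS & high FW, and the two
mixed profiles pooled as discordant (FW's favorable side is at-or-below
its threshold). All three pairwise log-rank tests are reported.

## The synthetic-data generator

`make_phantom()` builds axis-aligned tensor grids: projection-fiber blocks
(principal axis z), association blocks (axis y), optional tumor and CSF
compartments, a per-voxel free-water ground truth, and an optional
perivascular `dxx_elevation` that raises x-diffusivity in both fiber
systems — the geometry the ALPS index is designed to detect.
`simulate_dwi()` applies the bi-tensor forward model and Rician noise
(magnitude MRI; `snr` defined on the b0 signal; a Gaussian option exists
for debugging). Emulated acquisitions: b = 0 + 1000 s/mm² with 31–124
directions and b = 0 + 2000 s/mm² with 56 directions, directions from a
deterministic Fibonacci spiral.

`simulate_cohort()` draws two-site cohorts whose defaults are the study
conditions the package targets: 277/269 subjects, age ~ N(63, 11), ~60%
male, ALPS ~ N(1.40, 0.15), FW ~ N(0.21, 0.05), ipsilateral ROI-category
frequencies ~68/25/5/2% (iNAWM/FLAIR/enhancing/necrosis), per-SD log
hazard ratios −0.3 (ALPS) and +0.3 (FW) matching multivariate HRs of about
0.75 and 1.34, age +0.25/SD, and a Weibull baseline (scale 550 days,
shape 1.2, median OS ≈ 15 months). Site effects distort observed
biomarkers as shift-then-scale about the site mean; the pre-distortion
values are retained for parameter-recovery tests. Survival times are
inverse-sampled from the Weibull proportional-hazards model; censoring is
independent uniform with the horizon calibrated by root-finding to the
target fraction (the real cohorts' censoring fraction is unpublished, so
it is a free parameter, default 0.3). Eligibility fields emulate the
selection process: ~2% bilateral tumors and a midline-shift distribution
leaving ~7% above the 5-mm exclusion limit, so the filters have work to do.
`simulate_changepoint_cohort()` plants a step (hazard doubling below a
threshold) rather than a log-linear effect — the regime the cutpoint scan
is built to recover.

What the generator does *not* emulate: scanner artifacts (eddy currents,
Gibbs ringing, motion — upstream preprocessing concerns), registration and
ROI-placement error (data are generated in a common grid; the
template-to-native chain is out of scope), partial-volume anatomy,
non-proportional hazards, and informative censoring. Passing tests
therefore demonstrate correctness of the estimators under the stated
models, not robustness to every artifact of real acquisitions.

## Problem sizes and numerical conventions

Desk-scale sizes are used throughout: 32³ voxel phantoms for ALPS
(agreement with the analytic index within 3% at SNR 40), 16³ for FW
recovery, cohorts of 200–600 subjects for harmonization and survival
checks, 100–200 replicates for recovery rates and 1000 for the log-rank
type-I calibration. Voxel indices follow R's 1-based convention with world
coordinates `index × voxel_size` and no affine rotations in synthetic
space; sex is coded 0/1; the midline-shift exclusion is strict (> 5 mm
excluded, 5 mm retained). `run_cohort()` orchestrates the table-level
stages on subject records (simulated, or collected from per-subject
imaging via `run_subject()`, which quarantines per-subject failures with
warnings instead of aborting); the whole run is deterministic given its
input table, and `write_cohort_run()` output is byte-identical across
repeated runs.

## Known limitations

* Single-shell FW estimation is fundamentally limited (see above); means
  over regions are trustworthy, individual voxels are not.
* EB shrinkage pools over a handful of features, so scale estimates shrink
  toward the cross-feature mean when features disagree; with strongly
  heterogeneous site effects per feature, harmonize features separately.
* The cutpoint scan's selected p-value is optimistically biased by
  construction; only the fixed-threshold validation p should be quoted.
* ROI placement assumes the phantom/native-space masks are supplied;
  atlas registration and manual correction are out of scope.
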