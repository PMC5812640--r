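---
title: "Methods: variable-flip-angle R1 mapping and dose-stratified R1-ratio analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variable-flip-angle R1 mapping and dose-stratified R1-ratio analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(r1ratio)
```

## Scope

`r1ratio` measures radiotherapy-associated change in the longitudinal
relaxation rate R1 = 1/T1 of brain tissue. It covers four stages: a digital
brain phantom that generates multi-flip-angle image sets with known ground
truth; variable-flip-angle (VFA) R1 map fitting; dose-stratified
region-of-interest (ROI) measurement of pre/post-radiotherapy R1 and their
ratio; and the cohort-level statistical battery. This vignette documents
the model, every tunable that matters, the numerical conventions, and what
the synthetic validation does and does not establish about real data.

## The signal model and its fit

The spoiled gradient-echo steady-state signal at flip angle $\alpha$ is

$$SI = S_0 \sin\alpha \,\frac{(1-E_1)\,E_2}{1-E_1\cos\alpha},
\qquad E_1 = e^{-TR/T1},\quad E_2 = e^{-TE/T2^*}.$$

`spgr_signal()` evaluates this full form. With $TE \ll T2^*$
($E_2 \to 1$) the model linearizes to

$$\frac{SI}{\sin\alpha} = E_1\,\frac{SI}{\tan\alpha} + S_0(1-E_1),$$

a line in $(x, y) = (SI/\tan\alpha,\ SI/\sin\alpha)$ whose slope is $E_1$.
`vfa_fit()` fits this line per voxel by unweighted ordinary least squares
and converts the slope to $T1 = -TR/\ln E_1$ (ms) and $R1 = 1000/T1$
(s⁻¹). Three properties anchor the design and are enforced by tests:

* **Exactness.** On noiseless signals the fit inverts the forward model to
  floating-point precision for any protocol with ≥ 2 distinct flip angles
  in (0°, 90°).
* **$E_2$ cancellation.** $E_2$ multiplies both $x$ and $y$, so a finite
  $T2^*$ leaves the slope — hence R1 — unchanged. TE therefore never biases
  the estimate, only the signal amplitude.
* **Scale invariance.** Rescaling all signals rescales only the intercept.

**Weighting.** The linearization makes the effective noise on $(x, y)$
heteroscedastic across angles and correlated between coordinates (the same
measured SI appears in both). We deliberately fit *unweighted* OLS — the
convention of the clinical processing chain this mirrors — and document
rather than correct the consequence: at low signal-to-noise ratio the slope
estimate is biased (see *Limitations*).

**Validity masking.** A voxel is valid only when every signal is strictly
positive, the slope lies in the open interval (0, 1) — the boundary values
would mean $T1 = \infty$ or $\log 0$ — and the implied R1 falls in
`r1_limits = c(0.05, 10)` s⁻¹. That range brackets the physiologic brain
range (roughly 0.48–0.88 s⁻¹ across deep grey and white matter) with a
wide margin; it rejects air and noise-only voxels without touching tissue.
Invalid voxels carry a reason code (`nonpositive_signal`,
`slope_out_of_range`, `r1_out_of_range`, `singular_fit`) and per-reason
counts travel in the map's provenance, because the clinical tools this
emulates do not document their masking and we want ours auditable.

**Default protocol.** TR/TE 4/1.4 ms, flip angles 2°, 8° and 15°,
192 × 192 matrix over 240 × 240 mm, 3 mm slices — a standard 3T VIBE R1
protocol. With TR = 4 ms the signal is strongly saturated: at
$S_0 = 1000$, T1 = 1266 ms the three angles yield SI ≈ 29.3, 34.2 and
22.0, i.e. only 2–3.5 % of $S_0$. That ratio matters for noise behaviour
(below).

## The phantom

`build_phantom()` constructs, on a common grid, a head ellipsoid containing
ten mirrored anatomical regions (thalamus, globus pallidus,
frontal/parietal/temporal white matter × left/right, spheres at fixed
world-mm positions), a spherical resection cavity with a surrounding
peri-tumoral shell on the tumor side, ground-truth maps (baseline R1,
$S_0$, $T2^*$), and a radiation dose field. Key choices:

* **Baseline R1.** Regional means default to values typical of 3T brain
  relaxometry (thalamus 0.49–0.51, globus pallidus 0.62–0.64, white matter
  0.73–0.88, peri-tumoral tissue 0.7901 s⁻¹, SDs of 0.03–0.10 across
  patients). Multiplicative voxel jitter (SD 0.5 %) adds texture without
  moving regional means by more than 1 %.
* **Dose model.** Isotropic exponential falloff from the tumor centre,
  $D(r) = D_{max}\,2^{-r/r_{1/2}}$ with $r_{1/2} = 35$ mm. Real planning
  dose maps are CT-based and not reproducible from a specification; this
  radial model is chosen so that the peri-tumoral shell (outer radius
  20 mm) lies entirely inside the 50–100 % iso-dose band, the ipsilateral
  frontal and temporal white matter straddle into it, and every
  contralateral region stays below 50 % — the geometry the dose-class
  analysis assumes, enforced voxelwise by tests.
* **Noise.** Additive Gaussian noise on signal magnitude is the default,
  because the downstream fit is an unweighted linear regression and the
  acquisition's SNR regime is not specified; Rician (magnitude) noise is
  available via `rician = TRUE`.
* **Grid.** Default 96 × 96 × 24 voxels at 2.5 × 2.5 × 3 mm — the clinical
  field of view at half the in-plane resolution, chosen so a whole-volume
  simulate-and-fit pass runs in well under a second and the full test
  suite in tens of seconds. Pass `grid_dim = c(192, 192, 24)`,
  `voxel_mm = c(1.25, 1.25, 3)` for the full clinical matrix.
* **Units and coordinates.** R1 is stored in s⁻¹ everywhere; T1 exists in
  ms only inside the relaxometry conversion (R1 = 1000/T1 at one
  boundary). World coordinates are millimetres on a grid centred at the
  origin; all of a patient's volumes share one grid, i.e. the phantom
  assumes perfect co-registration (the clinical workflow registers
  implicitly; modelling misregistration is out of scope).

`apply_radiation_effect()` produces post-radiation ground truth as
baseline R1 × a dose-class- and radiotherapy-type-specific ratio: routine
radiotherapy 1.0463 and hypofractionated 0.9913 in high-dose tissue,
0.9882 below the 50 % surface, with optional per-region Gaussian noise on
the ratio (one draw per labelled region, emulating patient-level
variability in an ROI-mean analysis rather than voxel noise).

## Cohort generation

`simulate_covariates()` draws a 44-patient cohort (33 routine /
11 hypofractionated) with age 54.3 ± 15.2 y (hypofractionated patients
older, which induces the age–RT-type association a cohort like this
shows), 29 M / 15 F, gadobutrol 5.1 ± 1.8 vials (range 2–11), scan
interval 4.2 ± 2.1 months, total dose 61.1 ± 1.9 Gy (routine) or 45.0 Gy
(hypofractionated), serum creatinine back-computed from a target
MDRD eGFR of 93.8 ± 21.5 (so about half the cohort sits at ≥ 90),
log-normal liver markers giving roughly a quarter abnormal hepatic
function, two steroid users, and 38/6 imaging before/after adjuvant
temozolomide.

`simulate_measurements()` emulates the *outcome* of the ROI workflow
directly at table level: regional baselines from the configured
distributions, ratios from the effect distributions — peri-tumoral ratio
by radiotherapy type (1.0463 ± 0.0633 routine, 0.9913 ± 0.0740
hypofractionated; population mean ≈ 1.032), anatomical high-dose regions
1.0055 ± 0.0654 and low-dose 0.9882 ± 0.0642. The anatomical high-dose
effect is deliberately calibrated *weaker* than the peri-tumoral one, as
dose-class analyses of named regions show; the voxel-level
`apply_radiation_effect()` keeps a single high-dose ratio by default and
exposes `anatomical_high` for the same distinction. A second-observer
column (independent N(0, 0.01 s⁻¹) measurement noise) supports the
reproducibility analysis, and a 10-patient subset carries a long-term
final R1 (final/baseline ratio 1.0384 ± 0.0909).

This table-level generator is what the replication analyses run on; the
image-level path (`generate_cohort(write_images = TRUE)` and
`run_study()`) exercises the identical measurement chain through actual
NIfTI volumes, map fitting and ROI placement, and is validated on small
cohorts. The split keeps a 50-cohort replication study to seconds while
the imaging chain is still tested end to end.

## ROI rules

* **Dose class** is assigned at the region centroid (nearest in-mask voxel
  to the centroid for non-convex masks): ≥ 50 % of the maximum dose is
  high. The 50 % boundary is *inclusive* — "within 50–100 %" is read as a
  closed interval — pinned by a unit test so the convention cannot drift.
  A centroid is a reproducible proxy for the qualitative judgement a
  reader makes about a whole named region.
* **Peri-tumoral ROIs.** Three circular single-slice ROIs (target area
  93.2 mm², radius $\sqrt{A/\pi}$; the voxelized footprint stays within
  15 % of the target area) must lie entirely inside
  shell ∩ high-dose, avoid the enhancing and T2-abnormal overlays
  entirely, and keep pairwise centre distances ≥ 20 mm in *world*
  millimetres (slice thickness ≠ in-plane spacing, so voxel-index
  distances would be wrong). Manual placement is not reproducible, so
  placement is deterministic: first feasible position in raster order,
  then farthest-point (max–min distance) selection — determinism is
  preferred over realism. Infeasibility errors name the violated
  constraint. The same ROI coordinates are used at both timepoints.
* **Anatomical regions** are measured once per area over their full
  extent ("maximal coverage"); regions intersecting the T2-abnormal
  overlay are recorded unmeasurable rather than dropped. The dentate
  nucleus is excluded outright (its R1 is unreliable under aliasing in
  this acquisition), mirrored by omitting it from the phantom.
* **Ratios** are computed per patient and region (post/pre of that
  patient's means), then averaged across patients — not ratios of
  averaged R1.

## Statistical battery

* **Normality gate.** Lilliefors-corrected one-sample Kolmogorov–Smirnov
  test at α = 0.05 on each sample (`nortest::lillie.test`): a plain KS
  test with parameters estimated from the data is anti-conservative.
  `lillie.test` needs n ≥ 5; for 3 ≤ n < 5 Shapiro–Wilk stands in. Both
  samples normal → paired/unpaired Student's t; otherwise Wilcoxon
  signed-rank (paired) or Mann–Whitney U (unpaired). The test actually
  applied is recorded in the result next to the gate outcome, and for
  group sizes ≤ 7 the Mann–Whitney p-value is verified against exhaustive
  enumeration of the null in the test suite.
* **Regression.** Univariate OLS per covariate (coefficient, SE, t-based
  95 % CI, p), then stepwise multiple regression with p-value entry < 0.05
  and removal > 0.1 using partial t-tests; ties broken by smallest p then
  input order; every enter/remove decision is logged and the log replays
  to the final model. With no qualifying candidate the model is empty with
  R² = 0 by definition.
* **Reproducibility.** ICC(2,1) — two-way random effects, absolute
  agreement, single measures, computed from the ANOVA mean squares — is
  the appropriate form for two raters measuring the same subjects, and the
  form is recorded in the output since "ICC" alone is ambiguous.
  Bland–Altman limits are mean difference ± 1.96 SD. The coefficient of
  variation is defined (there is no single convention) as the SD of the
  within-pair differences over the grand mean, × 100.
* **Clinical covariates.** eGFR by the 4-variable IDMS-traceable MDRD
  equation (constant 175); hepatic function abnormal when AST > 40, ALT
  > 40, GGT > 63 IU/L or total bilirubin > 1.2 mg/dL — strictly greater,
  so threshold values are normal. Chi-squared tests are Pearson without
  continuity correction; sub-1 expected counts raise a recorded warning.
* **No multiple-testing correction** is applied anywhere, and the report
  footer says so; the tables are descriptive of one pre-specified
  contrast family.

## Problem sizes and tolerances

Noiseless relaxometry must round-trip T1 over 300–3000 ms to relative
error < 1e−9 (it achieves ~1e−13; the tolerance allows for platform
arithmetic differences), scale-invariance and $E_2$ cancellation to
< 1e−12. The whole-volume roundtrip on the default grid is checked to
1e−6 s⁻¹. Replication analyses use 50 cohorts of 44 patients; the noise
study uses 10⁴ voxels; OLS is verified against the normal equations to
1e−10. The acceptance script (`scripts/acceptance.R`) recomputes all of
these from scratch at a caller-supplied seed.

## Limitations

* **Linearized-fit bias at low SNR.** Because SI is only 2–3.5 % of $S_0$
  at TR = 4 ms, noise specified relative to $S_0$ is large relative to
  the signal: an SD of 1 % of $S_0$ is ~30–45 % of SI itself (per-angle
  SNR ≈ 2–3). In that regime the correlated noise shared by $x$ and $y$
  biases the OLS slope and even the *median* fitted R1 sits several
  percent from truth — the unweighted linearized estimator is simply not
  reliable at single-digit SNR, and the package documents this rather than
  silently reweighting. At realistic SNR (noise ~1 % of the *signal*) the
  median error is far inside 2 %.
* **Replication of marginal effects.** With 44 patients and a
  between-patient ratio SD near 0.07, a mean peri-tumoral ratio of ~1.03
  gives a paired-test noncentrality around 3: such an effect reaches
  p < .01 in only roughly six of ten replicate cohorts, and a stepwise
  screen retains the radiotherapy-type predictor alone in about half. The
  acceptance script measures and reports these replication rates; a
  single cohort's significant result should be read with that sampling
  variability in mind.
* **Schematic anatomy.** The phantom's spherical regions, radial dose
  field, and perfect pre/post alignment validate the *computational*
  chain — they say nothing about segmentation error, registration error,
  B1 transmit inhomogeneity (uncorrected here, as in the mirrored
  clinical workflow), partial-volume effects or scanner drift in real
  data.
* **Deposited-data reproduction.** `reproduce_study()` re-runs the
  identical analysis on an external per-patient table through a
  column-mapping configuration (deposited spreadsheets have no standard
  headers). The packaged example table is a synthetic stand-in with that
  layout, used to verify the mapped path against independent
  recomputation from the file.
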