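# r1ratio

Quantitative R1 relaxometry and longitudinal R1-ratio analysis for
radiotherapy-treated brain.

## The problem

After brain radiotherapy with repeated gadolinium-enhanced MRI, the
longitudinal relaxation rate R1 = 1/T1 (units s⁻¹) of irradiated tissue can
drift upward — T1 shortening consistent with gadolinium retention where the
blood–brain barrier has been damaged. Detecting that drift requires
*absolute* R1 maps (not signal-intensity ratios), reproducible region
measurements stratified by planned radiation dose, and a careful paired
statistical analysis. `r1ratio` implements that whole chain for
neuro-imaging researchers:

1. **Relaxometry** — variable-flip-angle (VFA/DESPOT1) T1 mapping from
   spoiled gradient-echo (SPGR/VIBE) images,
2. **Phantom** — a seeded digital brain phantom with a radiation dose field
   so the pipeline is fully testable without patient data,
3. **ROI analysis** — dose-stratified region measurement and post/pre R1
   ratios,
4. **Cohort statistics** — the normality-gated test battery, regression
   screen and reproducibility metrics such a study reports.

## The model

The SPGR steady-state signal at flip angle α is

    SI = S0 · sin α · (1 − E1) · E2 / (1 − E1 · cos α),
    E1 = exp(−TR/T1),   E2 = exp(−TE/T2*).

For TE ≪ T2* the E2 factor is ≈ 1 and the equation linearizes to

    SI/sin α = E1 · (SI/tan α) + S0 (1 − E1),

so an ordinary least-squares line through the points
(SI/tan α, SI/sin α) over several flip angles has slope E1, giving
T1 = −TR / ln(E1) and R1 = 1000/T1 per voxel. Because E2 multiplies both
coordinates it cancels in the slope, which is also invariant to global
signal scaling. Per-region post/pre-radiotherapy ratios
(R1 ratio = R1_post / R1_pre) are the primary statistic; regions at ≥ 50 %
of the maximum planned dose are "Area_H", the rest "Area_L".

## Worked example

```r
library(r1ratio)

ph <- build_phantom(phantom_config(), seed = 1)
ph <- apply_radiation_effect(ph, radiation_effect(), rt_type = "routine")
p  <- acquisition_protocol()        # TR/TE 4/1.4 ms, flip angles 2/8/15 deg

pre  <- fit_map(simulate_spgr_series(ph, p, noise_sd = 0, seed = 1, "pre"))
post <- fit_map(simulate_spgr_series(ph, p, noise_sd = 0, seed = 1, "post"))
pre
#> R1 map: grid 96x96x24, 56128/221184 voxels valid
#>   R1 (1/s): 0.2472-0.8954, median 0.6502

tab <- measure_patient(pre, post, ph, patient_id = "demo")
tab[tab$region %in% c("peritumoral", "thalamus", "frontal_wm"), 1:8]
#>    patient_id      region  side dose_class pre_r1 post_r1 r1_ratio measurable
#> 1        demo    thalamus right        low 0.4882  0.4824   0.9882       TRUE
#> 2        demo    thalamus  left        low 0.5084  0.5024   0.9882       TRUE
#> 5        demo  frontal_wm right       high 0.8754  0.9002   1.0283       TRUE
#> 6        demo  frontal_wm  left        low 0.8819  0.8715   0.9882       TRUE
#> 11       demo peritumoral right       high 0.7906  0.8272   1.0463       TRUE
```

Only background voxels are masked invalid (the head contains 56 128
voxels, all fitted); the noiseless peri-tumoral ratio is exactly the
configured routine-radiotherapy effect 1.0463, ipsilateral white matter
inside the 50 % iso-dose surface is classified high-dose, and contralateral
regions show the low-dose ratio 0.9882.

A cohort-level analysis on a simulated 44-patient cohort
(33 routine / 11 hypofractionated):

```r
sim <- simulate_measurements(cohort_spec(), seed = 1)
rep <- build_tables(sim$measurements, sim$covariates)
rep$rt_type
#> RT type: routine 1.0434 vs hypofractionated 0.9930 (p = 0.0431)
rep$table3_dose_class[6, ]
#>    region high_mean high_sd high_n low_mean low_sd low_n p_value
#> 6 overall     1.004  0.0587     88   0.9913 0.0642   352 0.07943
```

i.e. the high-dose-area ratio exceeds the low-dose one, and routine
radiotherapy shows the larger peri-tumoral R1 increase — single-cohort
p-values fluctuate around the calibrated effect sizes, which is itself a
finding the replication analysis (below) quantifies.

A four-stage end-to-end run (simulate → fit → roi → analyze) with a
checksummed manifest:

```r
run_study("out/", spec = cohort_spec(n_routine = 2, n_hypo = 1, seed = 4))
```

A thin command-line wrapper for these entry points is installed at
`inst/cli/r1ratio.R`.

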