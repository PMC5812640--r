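test_that("default cohort has 44 patients split 33 routine / 11 hypofractionated", {
  cv <- simulate_covariates(cohort_spec(), seed = 3)
  expect_equal(nrow(cv), 44L)
  expect_equal(sum(cv$rt_type == "routine"), 33L)
  expect_equal(sum(cv$rt_type == "hypofractionated"), 11L)
  expect_equal(sum(cv$sex == "M"), 29L)
  expect_true(all(cv$gd_vials >= 2 & cv$gd_vials <= 11))
  expect_true(all(cv$total_dose_gy[cv$rt_type == "hypofractionated"] == 45))
})

test_that("covariate summaries sit near their configured targets", {
  cv <- simulate_covariates(cohort_spec(), seed = 3)
  expect_lt(abs(mean(cv$age_y) - 54.3) / 54.3, 0.10)
  expect_lt(abs(mean(cv$gd_vials) - 5.1) / 5.1, 0.10)
  expect_lt(abs(mean(cv$interval_months) - 4.2) / 4.2, 0.15)
  expect_lt(abs(mean(cv$egfr) - 93.8) / 93.8, 0.10)
  # roughly half the cohort above the eGFR 90 cut, some abnormal hepatic
  expect_gt(sum(cv$egfr >= 90), 12); expect_lt(sum(cv$egfr >= 90), 32)
  expect_gt(sum(cv$hepatic_function == "abnormal"), 2)
  # derived columns are consistent with the clinical formulas
  expect_equal(cv$egfr,
               round(egfr_mdrd(cv$scr_mg_dl, cv$age_y, cv$sex == "F"), 1))
  expect_equal(cv$hepatic_function,
               hepatic_flag(cv$ast, cv$alt, cv$ggt, cv$tbil))
})

test_that("cohort generation is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_cohort(cohort_spec(), d1, seed = 5)
  generate_cohort(cohort_spec(), d2, seed = 5)
  for (f in c("covariates.csv", "measurements.csv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  d3 <- withr::local_tempdir()
  generate_cohort(cohort_spec(), d3, seed = 6)
  expect_false(identical(readBin(file.path(d1, "measurements.csv"),
                                 "raw", 1e6),
                         readBin(file.path(d3, "measurements.csv"),
                                 "raw", 1e6)))
})

test_that("a single-patient cohort is valid and minimal", {
  spec <- cohort_spec(n_routine = 1, n_hypo = 0)
  sim <- simulate_measurements(spec, seed = 2)
  expect_equal(nrow(sim$covariates), 1L)
  expect_equal(nrow(sim$measurements), 11L)
  expect_true(all(sim$measurements$r1_ratio > 0))
})

test_that("measurement tables carry the calibrated effect structure", {
  sim <- simulate_measurements(cohort_spec(), seed = 17)
  m <- sim$measurements
  anat <- m[m$region != "peritumoral", ]
  expect_gt(mean(anat$r1_ratio[anat$dose_class == "high"]),
            mean(anat$r1_ratio[anat$dose_class == "low"]))
  peri <- m[m$region == "peritumoral", ]
  expect_equal(nrow(peri), 44L)
  expect_true(all(peri$dose_class == "high"))
  # high-dose anatomical regions are the ipsilateral frontal/temporal WM
  cv <- sim$covariates
  side <- cv$tumor_side[match(anat$patient_id, cv$patient_id)]
  expect_true(all(anat$region[anat$dose_class == "high"] %in%
                    c("frontal_wm", "temporal_wm")))
  expect_true(all(anat$side[anat$dose_class == "high"] ==
                    side[anat$dose_class == "high"]))
  # long-term subset present
  expect_equal(sum(is.finite(m$final_r1)), 10L)
})

test_that("effect calibration: grand mean peri-tumoral ratio near 1.0317", {
  spec <- cohort_spec()
  means <- vapply(1:100, function(s) {
    sim <- simulate_measurements(spec, seed = 1000 + s)
    mean(sim$measurements$r1_ratio[sim$measurements$region == "peritumoral"])
  }, numeric(1))
  expect_lt(abs(mean(means) - 1.0317), 0.01)
})

test_that("YAML cohort configs require a seed and reject unknown keys", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("n_routine: 10\nn_hypo: 5\nseed: 7", f)
  spec <- cohort_spec_from_yaml(f)
  expect_equal(spec$n, 15)
  expect_equal(spec$seed, 7)
  writeLines("n_routine: 10", f)
  expect_error(cohort_spec_from_yaml(f), "seed")
  writeLines("seed: 1\nbogus_key: 2", f)
  expect_error(cohort_spec_from_yaml(f), "unknown")
})

test_that("report tables reproduce the calibrated directions and structure", {
  sim <- simulate_measurements(cohort_spec(), seed = 7)
  rep <- build_tables(sim$measurements, sim$covariates)
  t3 <- rep$table3_dose_class
  overall <- t3[t3$region == "overall", ]
  expect_gt(overall$high_mean, overall$low_mean)
  expect_equal(nrow(rep$table2_regions), 11L)
  expect_equal(nrow(rep$table4_univariate), 7L)
  expect_gt(rep$rt_type$routine["mean"], rep$rt_type$hypofractionated["mean"])
  expect_gt(rep$peri_vs_contralateral$peri["mean"],
            rep$peri_vs_contralateral$contralateral_wm["mean"])
  expect_equal(rep$longterm$n, 10L)
  expect_gt(rep$reproducibility$icc$icc, 0.9)
  expect_output(print(rep), "Area_H")
})

test_that("single-patient report degrades gracefully (no p-values)", {
  sim <- simulate_measurements(cohort_spec(n_routine = 1, n_hypo = 0),
                               seed = 2)
  rep <- build_tables(sim$measurements, sim$covariates)
  expect_true(all(is.na(rep$table2_regions$p_value)))
  expect_equal(rep$table2_regions$pre_mean,
               sim$measurements$pre_r1[match(
                 rep$table2_regions$region,
                 ifelse(sim$measurements$region == "peritumoral",
                        "peritumoral",
                        paste(sim$measurements$region, sim$measurements$side,
                              sep = "_")))])
})

test_that("schema violations name the missing columns", {
  sim <- simulate_measurements(cohort_spec(), seed = 1)
  broken <- sim$measurements[, setdiff(names(sim$measurements),
                                       c("r1_ratio", "dose_class"))]
  expect_error(build_tables(broken, sim$covariates),
               "dose_class.*r1_ratio|r1_ratio.*dose_class")
  expect_error(build_tables(sim$measurements,
                            sim$covariates[, 1:3, drop = FALSE]),
               "missing column")
})
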