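#' Cohort specification for the synthetic study
#'
#' Defines the simulated study population and effect calibration: 44
#' patients split 33 routine / 11 hypofractionated radiotherapy; baseline
#' regional R1 levels typical of 3T brain relaxometry; a peri-tumoral
#' post/pre R1 ratio of 1.0463 (SD 0.0633) under routine and 0.9913
#' (SD 0.0740) under hypofractionated radiotherapy (population mean ~1.032);
#' anatomical high-dose regions at ratio 1.0055 (SD 0.0654) and low-dose
#' regions at 0.9882 (SD 0.0642); and clinical covariates (age 54.3 +/- 15.2
#' years with older hypofractionated patients, 29 M / 15 F, gadobutrol
#' 5.1 +/- 1.8 vials, 4.2 +/- 2.1 month interval, eGFR 93.8 +/- 21.5 with a
#' ~50/50 split at 90, ~10/44 abnormal hepatic function, 2 steroid users,
#' 38/6 pre/post-temozolomide imaging, a 10-patient long-term follow-up
#' subset with final ratio 1.0384 +/- 0.0909).
#'
#' @param n_routine,n_hypo Patients per radiotherapy type.
#' @param peri_ratio_routine,peri_ratio_hypo Mean (and `..._sd`) of the
#'   peri-tumoral R1 ratio per radiotherapy type.
#' @param peri_ratio_routine_sd,peri_ratio_hypo_sd Patient-level ratio SDs.
#' @param anat_high_ratio,anat_high_ratio_sd,anat_low_ratio,anat_low_ratio_sd
#'   Ratio calibration for anatomical regions by dose class.
#' @param peri_pre_mean,peri_pre_sd Baseline peri-tumoral R1 (1/s).
#' @param region_pre Data frame of per-region baseline means/SDs (defaults
#'   built in; columns `region`, `side`, `mean`, `sd`).
#' @param obs_noise_sd Inter-observer measurement noise SD (1/s) used for
#'   the second-observer columns.
#' @param n_longterm Size of the long-term follow-up subset.
#' @param final_ratio_mean,final_ratio_sd Final/baseline R1 ratio in that
#'   subset.
#' @param seed Default seed used when the generator is called without one.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_routine = 33, n_hypo = 11,
                        peri_ratio_routine = 1.0463,
                        peri_ratio_routine_sd = 0.0633,
                        peri_ratio_hypo = 0.9913,
                        peri_ratio_hypo_sd = 0.0740,
                        anat_high_ratio = 1.0055,
                        anat_high_ratio_sd = 0.0654,
                        anat_low_ratio = 0.9882,
                        anat_low_ratio_sd = 0.0642,
                        peri_pre_mean = 0.7901, peri_pre_sd = 0.0977,
                        region_pre = NULL,
                        obs_noise_sd = 0.01,
                        n_longterm = 10,
                        final_ratio_mean = 1.0384,
                        final_ratio_sd = 0.0909,
                        seed = 1) {
  if (n_routine < 1 || n_hypo < 0)
    stop("patient counts must be positive", call. = FALSE)
  sds <- c(peri_ratio_routine_sd, peri_ratio_hypo_sd, anat_high_ratio_sd,
           anat_low_ratio_sd, obs_noise_sd)
  if (any(sds < 0)) stop("noise SDs must be >= 0", call. = FALSE)
  if (is.null(region_pre)) {
    region_pre <- data.frame(
      region = rep(c("thalamus", "gp", "frontal_wm", "parietal_wm",
                     "temporal_wm"), each = 2),
      side = rep(c("right", "left"), 5),
      mean = c(0.4882, 0.5086, 0.6235, 0.6385, 0.8749, 0.8815,
               0.7282, 0.7889, 0.7885, 0.8400),
      sd = c(0.0327, 0.0332, 0.0473, 0.0441, 0.0882, 0.0922,
             0.0547, 0.0425, 0.0500, 0.0784))
  }
  structure(list(
    n_routine = n_routine, n_hypo = n_hypo, n = n_routine + n_hypo,
    peri_ratio_routine = peri_ratio_routine,
    peri_ratio_routine_sd = peri_ratio_routine_sd,
    peri_ratio_hypo = peri_ratio_hypo,
    peri_ratio_hypo_sd = peri_ratio_hypo_sd,
    anat_high_ratio = anat_high_ratio,
    anat_high_ratio_sd = anat_high_ratio_sd,
    anat_low_ratio = anat_low_ratio, anat_low_ratio_sd = anat_low_ratio_sd,
    peri_pre_mean = peri_pre_mean, peri_pre_sd = peri_pre_sd,
    region_pre = region_pre, obs_noise_sd = obs_noise_sd,
    n_longterm = n_longterm, final_ratio_mean = final_ratio_mean,
    final_ratio_sd = final_ratio_sd, seed = seed),
    class = "cohort_spec")
}

#' Read a cohort specification from a YAML config
#'
#' The YAML keys mirror the arguments of [cohort_spec()]; a `seed` key is
#' mandatory.
#'
#' @param path Path to a YAML file.
#' @return A [cohort_spec()].
#' @export
cohort_spec_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set a seed", call. = FALSE)
  known <- names(formals(cohort_spec))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config key(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  do.call(cohort_spec, cfg)
}

rnorm_clamped <- function(n, mean, sd, lo = -Inf, hi = Inf)
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))

#' Simulate the clinical covariate table
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return Data frame with one row per patient: `patient_id`, `age_y`,
#'   `sex`, `rt_type`, `total_dose_gy`, `gd_vials`, `interval_months`,
#'   `scr_mg_dl`, `ast`, `alt`, `ggt`, `tbil`, `steroid_use`,
#'   `tmz_timing`, `tumor_side`, plus derived `egfr` and
#'   `hepatic_function`.
#' @export
simulate_covariates <- function(spec = cohort_spec(), seed = spec$seed) {
  set.seed(seed)
  n <- spec$n
  id <- sprintf("p%02d", seq_len(n))
  rt <- sample(rep(c("routine", "hypofractionated"),
                   c(spec$n_routine, spec$n_hypo)))
  # hypofractionation is given preferentially to older patients; means are
  # chosen so the cohort mean stays ~54.3 y
  age <- ifelse(rt == "routine",
                rnorm_clamped(n, 50.7, 14, 18, 85),
                rnorm_clamped(n, 65, 10, 18, 85))
  sex <- sample(rep(c("M", "F"), c(29, 15))[seq_len(n)])
  vials <- pmin(11, pmax(2, round(stats::rnorm(n, 5.1, 1.8))))
  interval <- rnorm_clamped(n, 4.2, 2.1, 0.5, Inf)
  dose <- ifelse(rt == "routine", rnorm_clamped(n, 61.1, 1.9, 55, 66), 45.0)
  egfr_target <- rnorm_clamped(n, 93.8, 21.5, 30, Inf)
  scr <- (egfr_target /
            (175 * age^(-0.203) * ifelse(sex == "F", 0.742, 1)))^(-1 / 1.154)
  ast <- stats::rlnorm(n, log(24), 0.35)
  alt <- stats::rlnorm(n, log(24), 0.35)
  ggt <- stats::rlnorm(n, log(30), 0.45)
  tbil <- stats::rlnorm(n, log(0.7), 0.3)
  steroid <- seq_len(n) %in% sample(n, min(2, n))
  tmz <- sample(rep(c("before_adjuvant_tmz", "after_adjuvant_tmz"),
                    c(max(0, n - 6), min(6, n)))[seq_len(n)])
  side <- sample(c("right", "left"), n, replace = TRUE)
  data.frame(
    patient_id = id, age_y = round(age, 1), sex = sex, rt_type = rt,
    total_dose_gy = round(dose, 1), gd_vials = vials,
    interval_months = round(interval, 1), scr_mg_dl = round(scr, 3),
    ast = round(ast, 1), alt = round(alt, 1), ggt = round(ggt, 1),
    tbil = round(tbil, 2), steroid_use = steroid, tmz_timing = tmz,
    tumor_side = side,
    egfr = round(egfr_mdrd(round(scr, 3), round(age, 1), sex == "F"), 1),
    hepatic_function = hepatic_flag(round(ast, 1), round(alt, 1),
                                    round(ggt, 1), round(tbil, 2)))
}

#' Simulate a cohort measurement table
#'
#' Emulates the per-patient, per-region outcome of the ROI workflow without
#' simulating images: baseline regional R1 values are drawn from the
#' configured regional distributions, the post/pre ratio from the
#' dose-class- and radiotherapy-type-specific effect distributions, and the
#' post value is their product.  Ipsilateral frontal and temporal white
#' matter are the high-dose anatomical regions (matching the phantom dose
#' geometry); the peri-tumoral area is always high-dose.  Second-observer
#' columns add independent measurement noise; a long-term `final_r1` is
#' filled for the follow-up subset.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; defaults to `spec$seed`.
#' @param covariates Optional covariate table from [simulate_covariates()]
#'   (regenerated from the same seed when missing).
#' @return List with `measurements` (data frame in the
#'   [measure_patient()] schema plus observer-2 and `final_r1` columns) and
#'   `covariates`.
#' @export
simulate_measurements <- function(spec = cohort_spec(), seed = spec$seed,
                                  covariates = NULL) {
  if (is.null(covariates)) covariates <- simulate_covariates(spec, seed)
  set.seed(seed + 1L)
  n <- nrow(covariates)
  longterm <- seq_len(n) %in% sample(n, min(spec$n_longterm, n))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cv <- covariates[i, ]
    rp <- spec$region_pre
    high <- rp$side == cv$tumor_side & rp$region %in%
      c("frontal_wm", "temporal_wm")
    pre <- stats::rnorm(nrow(rp), rp$mean, rp$sd)
    ratio <- ifelse(high,
                    stats::rnorm(nrow(rp), spec$anat_high_ratio,
                                 spec$anat_high_ratio_sd),
                    stats::rnorm(nrow(rp), spec$anat_low_ratio,
                                 spec$anat_low_ratio_sd))
    peri_pre <- stats::rnorm(1, spec$peri_pre_mean, spec$peri_pre_sd)
    peri_ratio <- if (cv$rt_type == "routine")
      stats::rnorm(1, spec$peri_ratio_routine, spec$peri_ratio_routine_sd)
    else stats::rnorm(1, spec$peri_ratio_hypo, spec$peri_ratio_hypo_sd)
    pre_all <- c(pre, peri_pre)
    post_all <- pre_all * c(ratio, peri_ratio)
    obs2_pre <- pre_all + stats::rnorm(length(pre_all), 0, spec$obs_noise_sd)
    obs2_post <- post_all + stats::rnorm(length(post_all), 0,
                                         spec$obs_noise_sd)
    final <- rep(NA_real_, length(pre_all))
    if (longterm[i])
      final[length(final)] <- peri_pre *
        stats::rnorm(1, spec$final_ratio_mean, spec$final_ratio_sd)
    rows[[i]] <- data.frame(
      patient_id = cv$patient_id,
      region = c(rp$region, "peritumoral"),
      side = c(rp$side, cv$tumor_side),
      dose_class = c(ifelse(high, "high", "low"), "high"),
      pre_r1 = pre_all, post_r1 = post_all,
      r1_ratio = post_all / pre_all,
      measurable = TRUE,
      n_voxels_pre = NA_integer_, n_voxels_post = NA_integer_,
      pre_r1_obs2 = obs2_pre, post_r1_obs2 = obs2_post,
      final_r1 = final)
  }
  list(measurements = do.call(rbind, rows), covariates = covariates)
}

#' Generate a full synthetic cohort on disk
#'
#' Writes the covariate CSV and either (fast path) the simulated
#' measurement table, or (image path) per-patient NIfTI bundles —
#' pre/post flip-angle series, dose map and label map — from which the
#' pipeline recomputes measurements by fitting R1 maps and placing ROIs.
#' Fully reproducible from the seed.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory.
#' @param seed Integer seed; defaults to `spec$seed`.
#' @param write_images If `TRUE`, simulate and write the image bundles
#'   (slow; intended for small grids / small cohorts).
#' @param phantom_cfg Base [phantom_config()] for the image path (tumor
#'   side is overridden per patient).
#' @param protocol Acquisition protocol for the image path.
#' @param noise_sd Signal noise SD for the image path.
#' @return Invisibly, a list with the covariate table, the measurement
#'   table (fast path only), and the paths written.
#' @export
generate_cohort <- function(spec = cohort_spec(), dir, seed = spec$seed,
                            write_images = FALSE,
                            phantom_cfg = phantom_config(),
                            protocol = acquisition_protocol(),
                            noise_sd = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_measurements(spec, seed)
  cov_path <- file.path(dir, "covariates.csv")
  utils::write.csv(sim$covariates, cov_path, row.names = FALSE)
  paths <- cov_path
  meas_path <- NULL
  if (!write_images) {
    meas_path <- file.path(dir, "measurements.csv")
    utils::write.csv(sim$measurements, meas_path, row.names = FALSE)
    paths <- c(paths, meas_path)
  } else {
    for (i in seq_len(nrow(sim$covariates))) {
      cv <- sim$covariates[i, ]
      cfg <- phantom_cfg
      cfg$tumor_side <- cv$tumor_side
      cfg$max_dose_cgy <- cv$total_dose_gy * 100 * 1.0365
      ph <- build_phantom(cfg, seed = seed + i)
      eff <- radiation_effect(
        high_routine = spec$peri_ratio_routine,
        high_hypo = spec$peri_ratio_hypo,
        low = spec$anat_low_ratio,
        anatomical_high = spec$anat_high_ratio,
        ratio_noise_sd = spec$peri_ratio_routine_sd)
      ph <- apply_radiation_effect(
        ph, eff, rt_type = if (cv$rt_type == "routine") "routine"
        else "hypofractionated", seed = seed + 1000L + i)
      pre <- simulate_spgr_series(ph, protocol, noise_sd,
                                  seed = seed + 2000L + i, "pre")
      post <- simulate_spgr_series(ph, protocol, noise_sd,
                                   seed = seed + 3000L + i, "post")
      paths <- c(paths,
                 write_flip_angle_series(pre, dir, cv$patient_id, "pre"),
                 write_flip_angle_series(post, dir, cv$patient_id, "post"))
      dpath <- file.path(dir, sprintf("%s_dose.nii.gz", cv$patient_id))
      lpath <- file.path(dir, sprintf("%s_labels.nii.gz", cv$patient_id))
      write_volume(ph$dose, dpath, ph$voxel_mm)
      write_volume(array(ph$labels, dim(ph$labels)), lpath, ph$voxel_mm,
                   datatype = "int16")
      paths <- c(paths, dpath, lpath)
    }
  }
  invisible(list(covariates = sim$covariates,
                 measurements = if (write_images) NULL else sim$measurements,
                 paths = paths))
}
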