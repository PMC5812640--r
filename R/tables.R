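required_meas_cols <- c("patient_id", "region", "side", "dose_class",
                        "pre_r1", "post_r1", "r1_ratio", "measurable")
required_cov_cols <- c("patient_id", "age_y", "sex", "rt_type", "gd_vials",
                       "interval_months", "egfr", "hepatic_function")

check_schema <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s table is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

mean_sd <- function(x) {
  x <- x[is.finite(x)]
  c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else NA_real_,
    n = length(x))
}

safe_gated_p <- function(a, b, paired) {
  if (paired) {
    ok <- is.finite(a) & is.finite(b)
    a <- a[ok]; b <- b[ok]
  } else {
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
  }
  if (length(a) < 3 || length(b) < 3) return(NA_real_)
  tryCatch(gated_compare(a, b, paired = paired)$p_value,
           error = function(e) NA_real_)
}

#' Build the study report from measurement and covariate tables
#'
#' Reproduces the study's result tables from a per-patient, per-region
#' measurement table (synthetic or imported): per-region pre/post R1 with a
#' normality-gated paired test; R1 ratios stratified by dose class
#' (Area_H vs Area_L) per region type and overall; the peri-tumoral vs
#' contralateral-white-matter ratio comparison; univariate linear
#' regressions of the peri-tumoral ratio on the clinical covariates;
#' stepwise multiple regression (entry p < 0.05, removal p > 0.1); subgroup
#' comparisons by radiotherapy type and by post-radiation imaging timing
#' relative to adjuvant temozolomide; the long-term follow-up summary when
#' `final_r1` is present; and inter-observer reproducibility (ICC(2,1),
#' Bland-Altman, CV) when observer-2 columns are present.  No
#' multiple-testing correction is applied.
#'
#' @param measurements Measurement table in the [measure_patient()] schema.
#' @param covariates Covariate table in the [simulate_covariates()] schema.
#' @return An object of class `study_report` (a list of data frames and
#'   test results).
#' @export
build_tables <- function(measurements, covariates) {
  check_schema(measurements, required_meas_cols, "measurement")
  check_schema(covariates, required_cov_cols, "covariate")
  m <- measurements[measurements$measurable %in% TRUE, ]

  # --- per-region pre/post (Table-2 analog) --------------------------------
  m$region_side <- ifelse(m$region == "peritumoral", "peritumoral",
                          paste(m$region, m$side, sep = "_"))
  regs <- unique(m$region_side)
  t2 <- do.call(rbind, lapply(regs, function(rs) {
    sub <- m[m$region_side == rs, ]
    pre <- mean_sd(sub$pre_r1); post <- mean_sd(sub$post_r1)
    data.frame(region = rs, n = unname(pre["n"]),
               pre_mean = unname(pre["mean"]), pre_sd = unname(pre["sd"]),
               post_mean = unname(post["mean"]), post_sd = unname(post["sd"]),
               p_value = safe_gated_p(sub$pre_r1, sub$post_r1, paired = TRUE))
  }))

  # --- dose-class ratios (Table-3 analog) ----------------------------------
  anat <- m[m$region != "peritumoral", ]
  t3_regions <- c("frontal_wm", "parietal_wm", "temporal_wm",
                  "thalamus", "gp")
  t3 <- do.call(rbind, lapply(c(t3_regions, "overall"), function(rg) {
    sub <- if (rg == "overall") anat else anat[anat$region == rg, ]
    h <- sub$r1_ratio[sub$dose_class == "high"]
    l <- sub$r1_ratio[sub$dose_class == "low"]
    hs <- mean_sd(h); ls <- mean_sd(l)
    data.frame(region = rg,
               high_mean = unname(hs["mean"]), high_sd = unname(hs["sd"]),
               high_n = unname(hs["n"]),
               low_mean = unname(ls["mean"]), low_sd = unname(ls["sd"]),
               low_n = unname(ls["n"]),
               p_value = safe_gated_p(h, l, paired = FALSE))
  }))

  # --- peri-tumoral vs contralateral white matter --------------------------
  peri <- m[m$region == "peritumoral", ]
  peri <- peri[match(covariates$patient_id, peri$patient_id), ]
  wm <- anat[grepl("_wm$", anat$region) & anat$dose_class == "low", ]
  contra <- stats::aggregate(r1_ratio ~ patient_id, data = wm, FUN = mean)
  peri_vs_contra <- list(
    peri = mean_sd(peri$r1_ratio),
    contralateral_wm = mean_sd(contra$r1_ratio),
    p_value = safe_gated_p(peri$r1_ratio[is.finite(peri$r1_ratio)],
                           contra$r1_ratio, paired = FALSE))

  # --- univariate regressions (Table-4 analog) -----------------------------
  cov <- covariates
  y <- peri$r1_ratio
  predictors <- list(
    age = cov$age_y,
    sex = as.numeric(factor(cov$sex)) - 1,
    gd_dose = cov$gd_vials,
    time_interval = cov$interval_months,
    rt_type = as.numeric(cov$rt_type == "routine"),
    hepatic_function = as.numeric(cov$hepatic_function == "abnormal"),
    egfr = cov$egfr)
  t4 <- do.call(rbind, lapply(names(predictors), function(nm) {
    u <- tryCatch(univariate_ols(y, predictors[[nm]]),
                  error = function(e) NULL)
    if (is.null(u))
      return(data.frame(variable = nm, coefficient = NA_real_, se = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        p_value = NA_real_))
    data.frame(variable = nm, coefficient = u$coefficient, se = u$se,
               ci_low = u$ci[1], ci_high = u$ci[2], p_value = u$p_value)
  }))

  ok <- is.finite(y)
  stepwise <- if (sum(ok) > 10)
    stepwise_ols(y[ok], as.data.frame(predictors)[ok, ]) else NULL

  # --- subgroup comparisons ------------------------------------------------
  rt_r <- peri$r1_ratio[cov$rt_type == "routine"]
  rt_h <- peri$r1_ratio[cov$rt_type == "hypofractionated"]
  rt_cmp <- list(routine = mean_sd(rt_r), hypofractionated = mean_sd(rt_h),
                 p_value = safe_gated_p(rt_r, rt_h, paired = FALSE))
  tmz_cmp <- NULL
  if ("tmz_timing" %in% names(cov)) {
    before <- peri$r1_ratio[cov$tmz_timing == "before_adjuvant_tmz"]
    after <- peri$r1_ratio[cov$tmz_timing == "after_adjuvant_tmz"]
    tmz_cmp <- list(before = mean_sd(before), after = mean_sd(after),
                    p_value = safe_gated_p(before, after, paired = FALSE))
  }

  # --- long-term follow-up subset ------------------------------------------
  longterm <- NULL
  if ("final_r1" %in% names(measurements)) {
    peri_all <- measurements[measurements$region == "peritumoral", ]
    lt <- peri_all[is.finite(peri_all$final_r1) &
                     peri_all$measurable %in% TRUE, ]
    fin <- lt$final_r1
    if (nrow(lt) >= 3) {
      final_ratio <- fin / lt$pre_r1
      longterm <- list(
        n = nrow(lt),
        pre = mean_sd(lt$pre_r1), post = mean_sd(lt$post_r1),
        final = mean_sd(fin),
        post_ratio = mean_sd(lt$r1_ratio),
        final_ratio = mean_sd(final_ratio),
        p_final_vs_post = safe_gated_p(final_ratio, lt$r1_ratio,
                                       paired = TRUE),
        p_final_vs_cohort = safe_gated_p(final_ratio, peri$r1_ratio,
                                         paired = FALSE))
    }
  }

  # --- inter-observer reproducibility --------------------------------------
  reproducibility <- NULL
  if (all(c("pre_r1_obs2", "post_r1_obs2") %in% names(measurements))) {
    mm <- measurements[measurements$measurable %in% TRUE, ]
    o1 <- c(mm$pre_r1, mm$post_r1)
    o2 <- c(mm$pre_r1_obs2, mm$post_r1_obs2)
    keep <- is.finite(o1) & is.finite(o2)
    if (sum(keep) >= 3) {
      ba <- bland_altman(o1[keep], o2[keep])
      reproducibility <- list(icc = icc(o1[keep], o2[keep]),
                              bland_altman = ba,
                              cv_percent = ba$cv_percent)
    }
  }

  structure(list(
    table2_regions = t2, table3_dose_class = t3,
    peri_vs_contralateral = peri_vs_contra,
    table4_univariate = t4, stepwise = stepwise,
    rt_type = rt_cmp, tmz_timing = tmz_cmp, longterm = longterm,
    reproducibility = reproducibility,
    footer = "No multiple-testing correction applied."),
    class = "study_report")
}

#' @export
print.study_report <- function(x, digits = 4, ...) {
  cat("== Per-region R1 before/after radiotherapy ==\n")
  print(format(x$table2_regions, digits = digits), row.names = FALSE)
  cat("\n== R1 ratio by radiation dose class (Area_H vs Area_L) ==\n")
  print(format(x$table3_dose_class, digits = digits), row.names = FALSE)
  cat(sprintf("\nPeri-tumoral ratio %.4f vs contralateral WM %.4f (p = %.3g)\n",
              x$peri_vs_contralateral$peri["mean"],
              x$peri_vs_contralateral$contralateral_wm["mean"],
              x$peri_vs_contralateral$p_value))
  cat("\n== Univariate regressions on the peri-tumoral R1 ratio ==\n")
  print(format(x$table4_univariate, digits = digits), row.names = FALSE)
  if (!is.null(x$stepwise)) { cat("\n"); print(x$stepwise) }
  cat(sprintf("\nRT type: routine %.4f vs hypofractionated %.4f (p = %.3g)\n",
              x$rt_type$routine["mean"], x$rt_type$hypofractionated["mean"],
              x$rt_type$p_value))
  if (!is.null(x$longterm))
    cat(sprintf("Long-term (n = %d): post ratio %.4f, final ratio %.4f (p = %.3g)\n",
                x$longterm$n, x$longterm$post_ratio["mean"],
                x$longterm$final_ratio["mean"], x$longterm$p_final_vs_post))
  if (!is.null(x$reproducibility))
    cat(sprintf("Inter-observer: ICC(2,1) = %.4f, CV = %.2f%%\n",
                x$reproducibility$icc$icc, x$reproducibility$cv_percent))
  cat(x$footer, "\n")
  invisible(x)
}

#' Write a study report to CSV tables and a JSON summary
#'
#' @param report A [build_tables()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of paths written, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("table2_regions", "table3_dose_class", "table4_univariate")) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(report[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(report$stepwise)) {
    p <- file.path(dir, "stepwise.csv")
    utils::write.csv(report$stepwise$coefficients, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  summ <- list(
    peri_vs_contralateral = report$peri_vs_contralateral,
    rt_type = report$rt_type, tmz_timing = report$tmz_timing,
    longterm = report$longterm,
    stepwise = if (!is.null(report$stepwise))
      list(selected = report$stepwise$selected,
           r_squared = report$stepwise$r_squared) else NULL,
    reproducibility = if (!is.null(report$reproducibility))
      list(icc = report$reproducibility$icc$icc,
           cv_percent = report$reproducibility$cv_percent,
           mean_diff = report$reproducibility$bland_altman$mean_diff,
           limits = report$reproducibility$bland_altman$limits) else NULL,
    footer = report$footer)
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(summ, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
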