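read_patient_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv")) {
    utils::read.csv(path, check.names = FALSE)
  } else if (ext %in% c("tsv", "txt")) {
    utils::read.delim(path, check.names = FALSE)
  } else if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading .xlsx requires the readxl package", call. = FALSE)
    as.data.frame(readxl::read_excel(path))
  } else stop("unsupported table format: .", ext, call. = FALSE)
}

#' Reproduce the study report from a deposited patient-level table
#'
#' Reads a one-row-per-patient table (CSV/TSV, or XLSX when readxl is
#' available) such as a study's deposited supplementary data file, reshapes
#' it into the package's measurement + covariate schema using a
#' column-mapping configuration, and runs the same [build_tables()] analysis
#' used for synthetic cohorts.  The mapping is external because deposited
#' files do not share a standard header layout.
#'
#' The mapping (YAML file or equivalent list) has three blocks:
#' \describe{
#'   \item{`patient_id`}{column holding the patient identifier.}
#'   \item{`covariates`}{named map from the package's covariate names
#'     (`age_y`, `sex`, `rt_type`, `gd_vials`, `interval_months`, `egfr`,
#'     `hepatic_function`, optionally `tmz_timing`, ...) to the file's
#'     column names.  `sex` values are normalised to `M`/`F`; `rt_type`
#'     values containing "hypo" (case-insensitive) become
#'     `hypofractionated`, all others `routine`.}
#'   \item{`regions`}{one entry per region (e.g. `peritumoral`,
#'     `thalamus_right`); each gives `pre` and `post` column names, an
#'     optional `final` column, an optional `side`, and either
#'     `dose_class` (fixed `"high"`/`"low"`) or `dose_class_column`.}
#' }
#'
#' @param path Path to the patient-level table.
#' @param mapping Path to a YAML mapping file, or the equivalent list.
#' @return A `study_report` (see [build_tables()]).
#' @export
reproduce_study <- function(path, mapping) {
  if (is.character(mapping)) mapping <- yaml::read_yaml(mapping)
  raw <- read_patient_table(path)
  need <- function(col) {
    if (!col %in% names(raw))
      stop("mapped column not found in table: ", col, call. = FALSE)
    raw[[col]]
  }
  id <- as.character(need(mapping$patient_id))

  cov <- data.frame(patient_id = id)
  for (nm in names(mapping$covariates))
    cov[[nm]] <- need(mapping$covariates[[nm]])
  if ("sex" %in% names(cov))
    cov$sex <- ifelse(toupper(substr(as.character(cov$sex), 1, 1)) %in%
                        c("F", "2"), "F", "M")
  if ("rt_type" %in% names(cov))
    cov$rt_type <- ifelse(grepl("hypo", cov$rt_type, ignore.case = TRUE),
                          "hypofractionated", "routine")
  for (nm in setdiff(required_cov_cols, names(cov)))
    cov[[nm]] <- NA

  rows <- lapply(names(mapping$regions), function(rg) {
    mp <- mapping$regions[[rg]]
    pre <- as.numeric(need(mp$pre))
    post <- as.numeric(need(mp$post))
    dc <- if (!is.null(mp$dose_class_column))
      as.character(need(mp$dose_class_column))
    else rep(mp$dose_class %||% if (rg == "peritumoral") "high" else "low",
             length(id))
    side <- mp$side %||% sub(".*_(right|left)$", "\\1", rg)
    if (!side %in% c("right", "left")) side <- "right"
    data.frame(patient_id = id,
               region = sub("_(right|left)$", "", rg),
               side = side, dose_class = tolower(dc),
               pre_r1 = pre, post_r1 = post, r1_ratio = post / pre,
               measurable = is.finite(pre) & is.finite(post),
               n_voxels_pre = NA_integer_, n_voxels_post = NA_integer_,
               final_r1 = if (!is.null(mp$final))
                 as.numeric(need(mp$final)) else NA_real_)
  })
  meas <- do.call(rbind, rows)
  build_tables(meas, cov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
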