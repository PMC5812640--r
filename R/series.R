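#' Flip-angle image series
#'
#' Container for co-registered SPGR volumes acquired at several flip angles,
#' one 3D array per angle on a shared grid, plus the acquisition protocol and
#' voxel dimensions.
#'
#' @param volumes List of numeric 3D arrays, one per protocol flip angle, all
#'   with identical dimensions and finite values.
#' @param protocol An [acquisition_protocol()].
#' @param voxel_mm Voxel dimensions in mm (length 3).
#' @return An object of class `flip_angle_series`.
#' @export
flip_angle_series <- function(volumes, protocol, voxel_mm = c(2.5, 2.5, 3)) {
  stopifnot(inherits(protocol, "acquisition_protocol"), is.list(volumes))
  if (length(volumes) != length(protocol$flip_angles_deg))
    stop("one volume per protocol flip angle required", call. = FALSE)
  d <- dim(volumes[[1]])
  if (length(d) != 3L) stop("volumes must be 3D arrays", call. = FALSE)
  for (v in volumes) {
    if (!identical(dim(v), d))
      stop("all volumes must share the same grid", call. = FALSE)
    if (any(!is.finite(v)))
      stop("signal volumes must be finite", call. = FALSE)
  }
  structure(list(volumes = volumes, protocol = protocol,
                 voxel_mm = as.numeric(voxel_mm), dim = d),
            class = "flip_angle_series")
}

#' @export
print.flip_angle_series <- function(x, ...) {
  cat(sprintf("Flip-angle series: %d volumes (%s deg), grid %s, voxels %s mm\n",
              length(x$volumes),
              paste(x$protocol$flip_angles_deg, collapse = "/"),
              paste(x$dim, collapse = "x"),
              paste(x$voxel_mm, collapse = "x")))
  invisible(x)
}

#' Fit an R1 map from a flip-angle series
#'
#' Applies the linearized variable-flip-angle fit ([vfa_fit()]) to every
#' voxel of a [flip_angle_series()] and returns a voxelwise R1 map (1/s)
#' with a validity mask.  Invalid voxels (non-positive signal, slope outside
#' (0, 1), R1 outside `r1_limits`) are `NA` in the map and `FALSE` in the
#' mask; per-reason counts are recorded in the provenance.
#'
#' @param series A [flip_angle_series()].
#' @param r1_limits Validity range for R1 in 1/s (default 0.05-10).
#' @return An object of class `r1_map`: list with `r1` (3D array, 1/s),
#'   `mask` (logical 3D array), `voxel_mm`, and `provenance`.
#' @examples
#' p <- acquisition_protocol()
#' gt <- array(1000 / 1266, c(4, 4, 2))          # T1 = 1266 ms everywhere
#' vols <- lapply(p$flip_angles_deg, function(a)
#'   array(spgr_signal(1000, 1000 / gt, p$tr_ms, a), dim(gt)))
#' m <- fit_map(flip_angle_series(vols, p))
#' range(m$r1, na.rm = TRUE)
#' @export
fit_map <- function(series, r1_limits = c(0.05, 10)) {
  stopifnot(inherits(series, "flip_angle_series"))
  d <- series$dim
  si <- vapply(series$volumes, as.vector, numeric(prod(d)))
  fit <- vfa_fit(si, series$protocol, r1_limits = r1_limits)
  r1 <- array(fit$r1_s, d)
  mask <- array(fit$valid, d)
  structure(
    list(r1 = r1, mask = mask, voxel_mm = series$voxel_mm,
         provenance = list(
           protocol = series$protocol,
           r1_limits = r1_limits,
           n_voxels = prod(d),
           n_invalid = sum(!fit$valid),
           invalid_reasons = table(fit$reason[!fit$valid])
         )),
    class = "r1_map"
  )
}

#' @export
print.r1_map <- function(x, ...) {
  cat(sprintf("R1 map: grid %s, %d/%d voxels valid\n",
              paste(dim(x$r1), collapse = "x"),
              sum(x$mask), x$provenance$n_voxels))
  if (any(x$mask))
    cat(sprintf("  R1 (1/s): %.4f-%.4f, median %.4f\n",
                min(x$r1, na.rm = TRUE), max(x$r1, na.rm = TRUE),
                stats::median(x$r1, na.rm = TRUE)))
  invisible(x)
}

# --- NIfTI I/O -------------------------------------------------------------

nifti_affine <- function(voxel_mm, dim) {
  # grid centred at world origin, RAS-ish diagonal affine
  aff <- diag(c(voxel_mm, 1))
  aff[1:3, 4] <- -voxel_mm * (dim - 1) / 2
  aff
}

write_volume <- function(vol, path, voxel_mm, datatype = "auto") {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- voxel_mm
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a flip-angle series to NIfTI files
#'
#' One `.nii.gz` file per flip angle, named
#' `<patient>_<tp>_fa<deg>.nii.gz`.
#'
#' @param series A [flip_angle_series()].
#' @param dir Output directory (created if absent).
#' @param patient Patient identifier used in file names.
#' @param tp Timepoint tag (e.g. `"pre"`, `"post"`).
#' @return Character vector of file paths, invisibly.
#' @export
write_flip_angle_series <- function(series, dir, patient, tp) {
  stopifnot(inherits(series, "flip_angle_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- series$protocol$flip_angles_deg
  paths <- file.path(dir, sprintf("%s_%s_fa%g.nii.gz", patient, tp, fa))
  for (i in seq_along(fa))
    write_volume(series$volumes[[i]], paths[i], series$voxel_mm)
  invisible(paths)
}

#' Read a flip-angle series from NIfTI files
#'
#' @param paths NIfTI file paths, ordered to match the protocol flip angles.
#' @param protocol The [acquisition_protocol()] of the acquisition.
#' @return A [flip_angle_series()].
#' @export
read_flip_angle_series <- function(paths, protocol) {
  vols <- lapply(paths, function(p) {
    img <- RNifti::readNifti(p)
    array(as.numeric(img), dim(img))
  })
  vox <- RNifti::pixdim(RNifti::readNifti(paths[1]))[1:3]
  flip_angle_series(vols, protocol, voxel_mm = vox)
}

#' Write an R1 map (value + mask) to NIfTI
#'
#' Writes `<patient>_<tp>_r1.nii.gz` (float, 1/s; invalid voxels 0) and
#' `<patient>_<tp>_r1mask.nii.gz` (uint8).
#'
#' @param map An `r1_map` from [fit_map()].
#' @param dir Output directory.
#' @param patient,tp Identifiers used in file names.
#' @return Character vector of the two paths, invisibly.
#' @export
write_r1_map <- function(map, dir, patient, tp) {
  stopifnot(inherits(map, "r1_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r1 <- map$r1; r1[!map$mask] <- 0
  p1 <- file.path(dir, sprintf("%s_%s_r1.nii.gz", patient, tp))
  p2 <- file.path(dir, sprintf("%s_%s_r1mask.nii.gz", patient, tp))
  write_volume(r1, p1, map$voxel_mm, datatype = "float")
  m <- array(as.integer(map$mask), dim(map$mask))
  write_volume(m, p2, map$voxel_mm, datatype = "uint8")
  invisible(c(p1, p2))
}
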