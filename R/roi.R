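#' Classify a dose value or region against the 50% iso-dose surface
#'
#' Tissue at or above 50% of the maximum planned dose is classified as a
#' high radiation dose area (`"high"`, Area_H); tissue below is low
#' (`"low"`, Area_L).  The 50% boundary is inclusive: a dose of exactly half
#' the maximum is high.  When a region mask is supplied the dose is
#' evaluated at the voxel nearest the region centroid (a reproducible proxy
#' for classifying a whole named region).
#'
#' @param dose A single dose value (cGy) or a 3D dose array.
#' @param max_dose_cgy Maximum dose (cGy); must be positive.
#' @param region_mask Optional logical array (required when `dose` is an
#'   array); must be non-empty.
#' @return A list of class `dose_class` with `dose_cgy`, `fraction`
#'   (dose / max), and `class` (`"high"` or `"low"`).
#' @examples
#' classify_dose(3600, 6343.8)  # 56.7% of maximum -> high
#' @export
classify_dose <- function(dose, max_dose_cgy, region_mask = NULL) {
  if (!is.numeric(max_dose_cgy) || max_dose_cgy <= 0)
    stop("maximum dose must be positive", call. = FALSE)
  if (!is.null(dim(dose))) {
    if (is.null(region_mask))
      stop("region_mask required for a dose volume", call. = FALSE)
    if (!any(region_mask)) stop("region mask is empty", call. = FALSE)
    idx <- which(region_mask, arr.ind = TRUE)
    ctr <- round(colMeans(idx))
    # nearest in-mask voxel to the centroid (centroid itself may fall
    # outside a non-convex mask)
    d2 <- rowSums(sweep(idx, 2L, ctr)^2)
    at <- idx[which.min(d2), , drop = TRUE]
    dose_val <- dose[at[1], at[2], at[3]]
  } else {
    stopifnot(length(dose) == 1L, dose >= 0)
    dose_val <- dose
  }
  frac <- dose_val / max_dose_cgy
  structure(list(dose_cgy = dose_val, fraction = frac,
                 class = if (frac >= 0.5) "high" else "low"),
            class = "dose_class")
}

#' @export
print.dose_class <- function(x, ...) {
  cat(sprintf("dose %.1f cGy = %.1f%% of maximum -> %s radiation dose area\n",
              x$dose_cgy, 100 * x$fraction, x$class))
  invisible(x)
}

# in-plane disc footprint: matrix of (di, dj) voxel offsets
disc_offsets <- function(radius_mm, voxel_mm) {
  r <- ceiling(radius_mm / voxel_mm[1:2])
  g <- expand.grid(di = -r[1]:r[1], dj = -r[2]:r[2])
  keep <- (g$di * voxel_mm[1])^2 + (g$dj * voxel_mm[2])^2 <= radius_mm^2
  as.matrix(g[keep, , drop = FALSE])
}

roi_voxels <- function(center, offsets, grid_dim) {
  v <- cbind(center[1] + offsets[, 1], center[2] + offsets[, 2],
             rep(center[3], nrow(offsets)))
  colnames(v) <- c("i", "j", "k")
  v
}

#' Place peri-tumoral measurement ROIs
#'
#' Deterministically places `n_rois` circular single-slice ROIs inside the
#' peri-tumoral shell, restricted to the high-dose (>= 50% iso-dose) region
#' and avoiding the enhancing and T2-abnormal overlays entirely, with
#' pairwise centre distances of at least `min_separation_mm` in world
#' millimetres.  The first ROI is the first feasible position in raster
#' (array) order; each subsequent ROI takes the feasible position farthest
#' (max-min distance) from those already chosen.
#'
#' @param phantom A [build_phantom()] result (supplies labels, overlays,
#'   dose and voxel dimensions).
#' @param n_rois Number of ROIs (default 3).
#' @param target_area_mm2 Target in-plane ROI area; the footprint radius is
#'   `sqrt(target_area_mm2 / pi)`.
#' @param min_separation_mm Minimum pairwise centre distance (ignored when
#'   `n_rois = 1`).
#' @return A list of `roi_spec` objects, each with `label`, `center`
#'   (voxel i, j, k), `radius_mm`, `area_mm2` (realized), and `voxels`
#'   (footprint voxel index matrix).
#' @export
place_peritumoral_rois <- function(phantom, n_rois = 3,
                                   target_area_mm2 = 93.2,
                                   min_separation_mm = 20) {
  stopifnot(inherits(phantom, "brain_phantom"), n_rois >= 1)
  gd <- dim(phantom$labels); vx <- phantom$voxel_mm
  shell <- phantom$labels == phantom$label_codes[["peritumoral"]]
  if (!any(shell)) stop("peri-tumoral shell absent", call. = FALSE)
  if (phantom$max_dose_cgy <= 0)
    stop("placement infeasible: no high-dose region (zero maximum dose)",
         call. = FALSE)
  allowed <- shell & phantom$dose >= 0.5 * phantom$max_dose_cgy &
    !phantom$enhancing & !phantom$t2_abnormal
  radius_mm <- sqrt(target_area_mm2 / pi)
  offs <- disc_offsets(radius_mm, vx)

  # a centre is feasible when its whole disc footprint is allowed
  feasible <- allowed
  for (r in seq_len(nrow(offs))) {
    sh <- shift_plane(allowed, offs[r, 1], offs[r, 2])
    feasible <- feasible & sh
  }
  cand <- which(feasible)
  if (length(cand) == 0L)
    stop("placement infeasible: no position keeps the ROI footprint inside ",
         "the high-dose, non-enhancing, T2-normal shell", call. = FALSE)

  co <- grid_coords(gd, vx)
  idx <- arrayInd(cand, gd)
  wx <- cbind(co[[1]][idx[, 1]], co[[2]][idx[, 2]], co[[3]][idx[, 3]])

  chosen <- 1L  # first feasible in raster order
  while (length(chosen) < n_rois) {
    d <- sapply(chosen, function(c0)
      sqrt(rowSums(sweep(wx, 2L, wx[c0, ])^2)))
    mind <- if (is.matrix(d)) apply(d, 1L, min) else d
    mind[chosen] <- -Inf
    best <- which.max(mind)
    if (mind[best] < min_separation_mm)
      stop(sprintf(paste0("placement infeasible: cannot satisfy the %g mm ",
                          "minimum ROI separation (best achievable %.1f mm)"),
                   min_separation_mm, mind[best]), call. = FALSE)
    chosen <- c(chosen, best)
  }
  area <- nrow(offs) * vx[1] * vx[2]
  lapply(seq_along(chosen), function(i) {
    ctr <- idx[chosen[i], ]
    structure(list(label = sprintf("peritumoral_roi%d", i),
                   center = ctr, radius_mm = radius_mm,
                   target_area_mm2 = target_area_mm2, area_mm2 = area,
                   voxels = roi_voxels(ctr, offs, gd)),
              class = "roi_spec")
  })
}

# shift a logical array in-plane by (di, dj), padding with FALSE
shift_plane <- function(a, di, dj) {
  d <- dim(a)
  out <- array(FALSE, d)
  si <- max(1, 1 - di):min(d[1], d[1] - di)
  sj <- max(1, 1 - dj):min(d[2], d[2] - dj)
  out[si, sj, ] <- a[si + di, sj + dj, , drop = FALSE]
  out
}

#' Mean R1 over an ROI
#'
#' Arithmetic mean of the valid voxels of an R1 map inside an ROI footprint
#' or a logical region mask.  Voxels outside the validity mask are ignored;
#' with no valid voxel the ROI is unmeasurable.
#'
#' @param map An `r1_map` from [fit_map()], or a plain list with numeric
#'   array `r1` and logical array `mask`.
#' @param roi An `roi_spec` (from [place_peritumoral_rois()]) or a logical
#'   array.
#' @return List with `mean` (`NA` if unmeasurable), `n_valid`, and
#'   `measurable`.
#' @export
roi_mean <- function(map, roi) {
  vox_vals <- if (inherits(roi, "roi_spec")) {
    v <- roi$voxels
    keep <- v[, 1] >= 1 & v[, 1] <= dim(map$r1)[1] &
      v[, 2] >= 1 & v[, 2] <= dim(map$r1)[2] &
      v[, 3] >= 1 & v[, 3] <= dim(map$r1)[3]
    v <- v[keep, , drop = FALSE]
    list(r1 = map$r1[v], ok = map$mask[v])
  } else {
    list(r1 = map$r1[roi], ok = map$mask[roi])
  }
  ok <- vox_vals$ok & is.finite(vox_vals$r1)
  if (!any(ok))
    return(list(mean = NA_real_, n_valid = 0L, measurable = FALSE))
  list(mean = mean(vox_vals$r1[ok]), n_valid = sum(ok), measurable = TRUE)
}

#' Measure all study regions for one patient
#'
#' Produces the per-region measurement table: the ten anatomical regions
#' (thalamus, globus pallidus, frontal/parietal/temporal white matter, both
#' sides, each measured once over its full extent) plus the peri-tumoral
#' area, whose value is the mean of `n_rois` circular ROI means placed by
#' [place_peritumoral_rois()] at identical positions pre and post.  Each
#' region is classified high/low dose at its centroid; regions intersecting
#' the T2-abnormal overlay are marked unmeasurable.
#'
#' @param map_pre,map_post `r1_map` objects on the phantom grid.
#' @param phantom The [build_phantom()] result supplying labels, overlays
#'   and dose.
#' @param patient_id Identifier copied into the table.
#' @param n_rois Number of peri-tumoral ROIs.
#' @return A data frame with columns `patient_id`, `region`, `side`,
#'   `dose_class`, `pre_r1`, `post_r1`, `r1_ratio`, `measurable`,
#'   `n_voxels_pre`, `n_voxels_post`.
#' @export
measure_patient <- function(map_pre, map_post, phantom, patient_id = "p1",
                            n_rois = 3) {
  stopifnot(inherits(phantom, "brain_phantom"))
  codes <- phantom$label_codes
  anat <- names(codes)[codes >= 10L]
  rows <- list()
  for (nm in anat) {
    mask <- phantom$labels == codes[[nm]]
    side <- sub(".*_(right|left)$", "\\1", nm)
    region <- sub("_(right|left)$", "", nm)
    t2_hit <- any(mask & phantom$t2_abnormal)
    dc <- classify_dose(phantom$dose, phantom$max_dose_cgy, mask)$class
    if (t2_hit) {
      rows[[nm]] <- data.frame(patient_id = patient_id, region = region,
                               side = side, dose_class = dc,
                               pre_r1 = NA_real_, post_r1 = NA_real_,
                               r1_ratio = NA_real_, measurable = FALSE,
                               n_voxels_pre = 0L, n_voxels_post = 0L)
      next
    }
    pre <- roi_mean(map_pre, mask); post <- roi_mean(map_post, mask)
    ok <- pre$measurable && post$measurable
    rows[[nm]] <- data.frame(
      patient_id = patient_id, region = region, side = side,
      dose_class = dc, pre_r1 = pre$mean, post_r1 = post$mean,
      r1_ratio = if (ok) post$mean / pre$mean else NA_real_,
      measurable = ok, n_voxels_pre = pre$n_valid,
      n_voxels_post = post$n_valid)
  }
  rois <- place_peritumoral_rois(phantom, n_rois = n_rois)
  pre_means <- vapply(rois, function(r) roi_mean(map_pre, r)$mean, 0)
  post_means <- vapply(rois, function(r) roi_mean(map_post, r)$mean, 0)
  n_pre <- sum(vapply(rois, function(r) roi_mean(map_pre, r)$n_valid, 0L))
  n_post <- sum(vapply(rois, function(r) roi_mean(map_post, r)$n_valid, 0L))
  ok <- all(is.finite(pre_means)) && all(is.finite(post_means))
  peri_pre <- if (ok) mean(pre_means) else NA_real_
  peri_post <- if (ok) mean(post_means) else NA_real_
  rows[["peritumoral"]] <- data.frame(
    patient_id = patient_id, region = "peritumoral",
    side = phantom$config$tumor_side, dose_class = "high",
    pre_r1 = peri_pre, post_r1 = peri_post,
    r1_ratio = if (ok) peri_post / peri_pre else NA_real_,
    measurable = ok, n_voxels_pre = n_pre, n_voxels_post = n_post)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
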