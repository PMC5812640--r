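#' Spoiled gradient-echo acquisition protocol
#'
#' Describes a 3D SPGR (VIBE-type) acquisition used for variable-flip-angle
#' T1 mapping.  The default corresponds to a clinical 3T brain protocol:
#' TR/TE 4/1.4 ms, flip angles 2, 8 and 15 degrees, 192 x 192 matrix over a
#' 240 x 240 mm field of view, 3 mm slices.
#'
#' @param tr_ms Repetition time in milliseconds; must be positive.
#' @param te_ms Echo time in milliseconds; must be positive.
#' @param flip_angles_deg Flip angles in degrees.  At least two distinct
#'   angles, each strictly inside (0, 90), are required for the linearized
#'   T1 fit.
#' @param matrix_size In-plane acquisition matrix (length 2).
#' @param fov_mm In-plane field of view in millimetres (length 2).
#' @param slice_thickness_mm Slice thickness in millimetres.
#'
#' @return An object of class `acquisition_protocol`.
#' @examples
#' acquisition_protocol()
#' @export
acquisition_protocol <- function(tr_ms = 4,
                                 te_ms = 1.4,
                                 flip_angles_deg = c(2, 8, 15),
                                 matrix_size = c(192L, 192L),
                                 fov_mm = c(240, 240),
                                 slice_thickness_mm = 3) {
  stopifnot(is.numeric(tr_ms), length(tr_ms) == 1L, tr_ms > 0)
  stopifnot(is.numeric(te_ms), length(te_ms) == 1L, te_ms > 0)
  fa <- as.numeric(flip_angles_deg)
  if (length(unique(fa)) < 2L)
    stop("at least two distinct flip angles are required", call. = FALSE)
  if (any(fa <= 0 | fa >= 90))
    stop("flip angles must lie strictly inside (0, 90) degrees", call. = FALSE)
  structure(
    list(tr_ms = tr_ms, te_ms = te_ms, flip_angles_deg = fa,
         matrix_size = as.integer(matrix_size), fov_mm = as.numeric(fov_mm),
         slice_thickness_mm = slice_thickness_mm),
    class = "acquisition_protocol"
  )
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat("SPGR acquisition protocol\n")
  cat(sprintf("  TR/TE: %g/%g ms\n", x$tr_ms, x$te_ms))
  cat(sprintf("  flip angles: %s deg\n",
              paste(x$flip_angles_deg, collapse = ", ")))
  cat(sprintf("  matrix %d x %d, FOV %g x %g mm, slices %g mm\n",
              x$matrix_size[1], x$matrix_size[2],
              x$fov_mm[1], x$fov_mm[2], x$slice_thickness_mm))
  invisible(x)
}
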