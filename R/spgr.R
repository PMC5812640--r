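#' SPGR steady-state signal
#'
#' Evaluates the full spoiled gradient-echo steady-state signal
#' \deqn{SI = S_0 \sin\alpha \, (1 - E_1) \, E_2 / (1 - E_1 \cos\alpha)}
#' with \eqn{E_1 = \exp(-TR/T1)} and \eqn{E_2 = \exp(-TE/T2^*)}.  With
#' `te_ms = 0` (or `t2star_ms = Inf`) the \eqn{E_2} factor is 1 and the
#' expression reduces to the short-TE form on which the linearized
#' variable-flip-angle fit is based.
#'
#' All arguments are vectorised and recycled against each other.
#'
#' @param s0 Equilibrium magnetisation (arbitrary signal units), >= 0.
#' @param t1_ms Longitudinal relaxation time in ms, > 0.
#' @param tr_ms Repetition time in ms, > 0.
#' @param alpha_deg Flip angle in degrees, in \[0, 90\].
#' @param te_ms Echo time in ms, >= 0.  Default 0 (no T2* decay).
#' @param t2star_ms Effective transverse relaxation time in ms, > 0.
#'   Default `Inf`.
#'
#' @return Signal intensity, same recycled length as the inputs.
#' @examples
#' spgr_signal(1000, 1266, 4, c(2, 8, 15))
#' @export
spgr_signal <- function(s0, t1_ms, tr_ms, alpha_deg, te_ms = 0,
                        t2star_ms = Inf) {
  if (any(t1_ms <= 0) || any(tr_ms <= 0) || any(t2star_ms <= 0))
    stop("relaxation and repetition times must be positive", call. = FALSE)
  if (any(te_ms < 0)) stop("te_ms must be >= 0", call. = FALSE)
  if (any(s0 < 0)) stop("s0 must be >= 0", call. = FALSE)
  if (any(alpha_deg < 0 | alpha_deg > 90))
    stop("alpha_deg must lie in [0, 90]", call. = FALSE)
  a <- alpha_deg * pi / 180
  e1 <- exp(-tr_ms / t1_ms)
  e2 <- exp(-te_ms / t2star_ms)
  s0 * sin(a) * (1 - e1) * e2 / (1 - e1 * cos(a))
}

#' Linearize a flip-angle signal series
#'
#' Maps SPGR signals measured at several flip angles to the linear form
#' \eqn{SI/\sin\alpha = E_1 \cdot SI/\tan\alpha + S_0 (1 - E_1)}, i.e. points
#' \eqn{(x, y) = (SI/\tan\alpha,\ SI/\sin\alpha)} whose slope is
#' \eqn{E_1 = \exp(-TR/T1)}.
#'
#' @param si Signal intensities, one per flip angle (vector, or a matrix with
#'   one column per angle for many voxels at once).
#' @param alpha_deg Flip angles in degrees, strictly inside (0, 90).
#'
#' @return A list with components `x` and `y`, each shaped like `si`.
#' @examples
#' si <- spgr_signal(1000, 1266, 4, c(2, 8, 15))
#' vfa_linearize(si, c(2, 8, 15))
#' @export
vfa_linearize <- function(si, alpha_deg) {
  if (any(alpha_deg <= 0 | alpha_deg >= 90))
    stop("linearization is degenerate at 0 or 90 degrees", call. = FALSE)
  if (any(!is.finite(si)))
    stop("signal intensities must be finite", call. = FALSE)
  a <- alpha_deg * pi / 180
  if (is.matrix(si)) {
    if (ncol(si) != length(a))
      stop("one signal column per flip angle required", call. = FALSE)
    list(x = sweep(si, 2L, tan(a), "/"), y = sweep(si, 2L, sin(a), "/"))
  } else {
    if (length(si) != length(a))
      stop("one signal per flip angle required", call. = FALSE)
    list(x = si / tan(a), y = si / sin(a))
  }
}

#' Convert a linearized-fit slope to R1
#'
#' The slope of the linearized variable-flip-angle fit equals
#' \eqn{E_1 = \exp(-TR/T1)}, so \eqn{T1 = -TR / \log(E_1)} (ms) and
#' \eqn{R1 = 1000 / T1} (1/s).  Slopes outside the open interval (0, 1) have
#' no physical T1 and yield `NA`.
#'
#' @param slope Fitted slope(s).
#' @param tr_ms Repetition time in ms.
#' @return R1 in 1/s (`NA` where the slope is not in (0, 1)).
#' @examples
#' r1_from_slope(exp(-4 / 1266), 4)  # ~0.79 1/s
#' @export
r1_from_slope <- function(slope, tr_ms) {
  stopifnot(tr_ms > 0)
  r1 <- rep(NA_real_, length(slope))
  ok <- is.finite(slope) & slope > 0 & slope < 1
  r1[ok] <- 1000 * (-log(slope[ok])) / tr_ms
  if (!is.null(dim(slope))) dim(r1) <- dim(slope)
  r1
}
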