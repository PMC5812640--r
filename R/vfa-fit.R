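#' Fit the variable-flip-angle T1 model
#'
#' Fits the linearized spoiled gradient-echo model to signals acquired at
#' several flip angles, one ordinary-least-squares line per voxel through the
#' points \eqn{(SI/\tan\alpha, SI/\sin\alpha)}.  The slope estimates
#' \eqn{E_1 = \exp(-TR/T1)}, from which T1 and R1 = 1000/T1 (1/s) follow; the
#' intercept estimates \eqn{S_0 (1 - E_1)}.
#'
#' A voxel is flagged valid only when every input signal is strictly
#' positive, the fitted slope lies strictly inside (0, 1), and the implied R1
#' falls inside `r1_limits`; other voxels carry a reason code
#' (`"nonpositive_signal"`, `"slope_out_of_range"`, `"r1_out_of_range"`,
#' `"singular_fit"`) and `NA` estimates.  The fit is unweighted: the
#' linearization makes the effective noise heteroscedastic across angles, but
#' no reweighting is applied (see the package vignette).
#'
#' @param si Signal intensities: a vector with one value per flip angle
#'   (a single voxel) or a matrix with one row per voxel and one column per
#'   flip angle.
#' @param protocol An [acquisition_protocol()]; its flip angles must match
#'   `ncol(si)`.
#' @param r1_limits Physiologically plausible R1 range in 1/s used for
#'   validity masking.  The default, 0.05 to 10, brackets brain tissue
#'   (roughly 0.5-0.9 1/s) with a wide margin and mostly rejects air and
#'   noise-only voxels.
#'
#' @return An object of class `vfa_fit` with components `slope`, `intercept`,
#'   `r_squared`, `t1_ms`, `r1_s`, `valid`, `reason`, `si`, `protocol`.
#' @seealso [fit_map()] for whole-volume fitting, [spgr_signal()] for the
#'   forward model.
#' @examples
#' p <- acquisition_protocol()
#' si <- spgr_signal(1000, 1266, p$tr_ms, p$flip_angles_deg)
#' fit <- vfa_fit(si, p)
#' coef(fit)
#' fit$r1_s  # ~0.79 1/s
#' @export
vfa_fit <- function(si, protocol = acquisition_protocol(),
                    r1_limits = c(0.05, 10)) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  one <- !is.matrix(si)
  m <- if (one) matrix(as.numeric(si), nrow = 1L) else si
  fa <- protocol$flip_angles_deg
  if (ncol(m) != length(fa))
    stop("need one signal per protocol flip angle", call. = FALSE)
  if (ncol(m) < 2L) stop("at least two flip angles required", call. = FALSE)

  pts <- vfa_linearize(m, fa)
  k <- length(fa)
  sx <- rowSums(pts$x); sy <- rowSums(pts$y)
  sxx <- rowSums(pts$x^2); sxy <- rowSums(pts$x * pts$y)
  syy <- rowSums(pts$y^2)
  den <- k * sxx - sx^2
  slope <- (k * sxy - sx * sy) / den
  intercept <- (sy - slope * sx) / k
  # R^2 of the linearized regression
  ss_tot <- syy - sy^2 / k
  ss_reg <- slope^2 * (sxx - sx^2 / k)
  r2 <- ifelse(ss_tot > 0, pmin(1, ss_reg / ss_tot), NA_real_)

  reason <- rep("ok", nrow(m))
  reason[!is.finite(slope)] <- "singular_fit"
  bad_sig <- rowSums(m <= 0) > 0
  reason[bad_sig] <- "nonpositive_signal"
  out_rng <- reason == "ok" & (slope <= 0 | slope >= 1)
  reason[out_rng] <- "slope_out_of_range"
  r1 <- r1_from_slope(slope, protocol$tr_ms)
  out_r1 <- reason == "ok" &
    (!is.finite(r1) | r1 < r1_limits[1] | r1 > r1_limits[2])
  reason[out_r1] <- "r1_out_of_range"
  valid <- reason == "ok"
  r1[!valid] <- NA_real_
  t1 <- ifelse(valid, 1000 / r1, NA_real_)
  slope[reason == "singular_fit"] <- NA_real_

  structure(
    list(slope = slope, intercept = intercept, r_squared = r2,
         t1_ms = t1, r1_s = r1, valid = valid, reason = reason,
         si = m, protocol = protocol, r1_limits = r1_limits,
         single = one),
    class = "vfa_fit"
  )
}

#' @export
print.vfa_fit <- function(x, ...) {
  n <- length(x$slope)
  cat(sprintf("Variable-flip-angle T1 fit: %d voxel%s, %d valid\n",
              n, if (n == 1) "" else "s", sum(x$valid)))
  cat(sprintf("  protocol: TR %g ms, angles %s deg\n", x$protocol$tr_ms,
              paste(x$protocol$flip_angles_deg, collapse = "/")))
  if (any(x$valid))
    cat(sprintf("  R1 (1/s): median %.4f, range %.4f-%.4f\n",
                stats::median(x$r1_s[x$valid]), min(x$r1_s[x$valid]),
                max(x$r1_s[x$valid])))
  invisible(x)
}

#' @export
summary.vfa_fit <- function(object, ...) {
  out <- list(
    n = length(object$slope),
    n_valid = sum(object$valid),
    reasons = table(object$reason),
    r1_summary = if (any(object$valid))
      summary(object$r1_s[object$valid]) else NULL,
    median_r2 = if (any(object$valid))
      stats::median(object$r_squared[object$valid]) else NA_real_
  )
  class(out) <- "summary.vfa_fit"
  out
}

#' @export
print.summary.vfa_fit <- function(x, ...) {
  cat(sprintf("VFA fit summary: %d/%d voxels valid\n", x$n_valid, x$n))
  print(x$reasons)
  if (!is.null(x$r1_summary)) {
    cat("R1 (1/s):\n"); print(x$r1_summary)
    cat(sprintf("median linearized R^2: %.6f\n", x$median_r2))
  }
  invisible(x)
}

#' @export
coef.vfa_fit <- function(object, ...) {
  cbind(slope = object$slope, intercept = object$intercept)
}

#' Predicted SPGR signals from a fitted VFA model
#'
#' @param object A [vfa_fit()] object.
#' @param alpha_deg Flip angles (degrees) at which to predict; defaults to
#'   the protocol angles.
#' @param ... Unused.
#' @return Matrix of predicted signals, voxels x angles.
#' @export
predict.vfa_fit <- function(object, alpha_deg = NULL, ...) {
  if (is.null(alpha_deg)) alpha_deg <- object$protocol$flip_angles_deg
  a <- alpha_deg * pi / 180
  # SI(a) = intercept * sin a / (1 - slope * cos a)
  out <- outer(object$intercept, sin(a)) /
    (1 - outer(object$slope, cos(a)))
  colnames(out) <- sprintf("fa%g", alpha_deg)
  out
}

#' @export
residuals.vfa_fit <- function(object, ...) {
  object$si - predict(object)
}

#' @export
fitted.vfa_fit <- function(object, ...) predict(object)

#' Simulate flip-angle signals from a fitted VFA model
#'
#' Draws replicate signal sets from the fitted per-voxel model with additive
#' Gaussian noise of standard deviation equal to the residual scale of each
#' voxel's fit (or `sd` if given).
#'
#' @param object A [vfa_fit()] object.
#' @param nsim Number of replicates.
#' @param seed Optional integer seed.
#' @param sd Noise standard deviation (signal units); default: per-voxel
#'   residual SD.
#' @param ... Unused.
#' @return A list of `nsim` signal matrices shaped like `object$si`.
#' @export
simulate.vfa_fit <- function(object, nsim = 1, seed = NULL, sd = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  if (is.null(sd)) {
    res <- object$si - mu
    sd <- sqrt(rowMeans(res^2))
  }
  lapply(seq_len(nsim), function(i)
    mu + matrix(stats::rnorm(length(mu), 0, sd), nrow = nrow(mu)))
}

#' Plot the linearized VFA fit
#'
#' Shows the linearized points \eqn{(SI/\tan\alpha, SI/\sin\alpha)} and the
#' fitted line for up to `max_voxels` voxels.
#'
#' @param x A [vfa_fit()] object.
#' @param max_voxels Maximum number of voxels to draw.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.vfa_fit <- function(x, max_voxels = 12, ...) {
  idx <- which(x$valid)
  if (length(idx) == 0L) idx <- seq_len(min(nrow(x$si), max_voxels))
  idx <- utils::head(idx, max_voxels)
  pts <- vfa_linearize(x$si[idx, , drop = FALSE],
                       x$protocol$flip_angles_deg)
  graphics::plot(range(pts$x), range(pts$y), type = "n",
                 xlab = expression(SI / tan(alpha)),
                 ylab = expression(SI / sin(alpha)), ...)
  for (j in seq_along(idx)) {
    i <- idx[j]
    graphics::points(pts$x[j, ], pts$y[j, ], pch = 19, col = j)
    if (is.finite(x$slope[i]))
      graphics::abline(x$intercept[i], x$slope[i], col = j, lty = 2)
  }
  invisible(x)
}
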