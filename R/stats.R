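ks_normal_p <- function(x) {
  # Lilliefors-corrected one-sample Kolmogorov-Smirnov test (parameters
  # estimated from the data); plain KS with estimated parameters is
  # anti-conservative.  lillie.test() needs n >= 5; fall back to
  # Shapiro-Wilk for 3 <= n < 5.
  if (stats::sd(x) == 0) return(0)  # constant: treat as non-normal
  if (length(x) >= 5) nortest::lillie.test(x)$p.value
  else stats::shapiro.test(x)$p.value
}

#' Normality-gated two-sample comparison
#'
#' Compares two samples the way a clinical analysis typically does: a
#' normality gate on each sample (Lilliefors-corrected Kolmogorov-Smirnov,
#' alpha = 0.05) decides between the parametric and rank-based test.  If
#' both samples pass, a paired or unpaired Student's t test is used;
#' otherwise the Wilcoxon signed-rank test (paired) or Mann-Whitney U /
#' rank-sum test (unpaired).
#'
#' @param a,b Numeric samples (equal length when `paired = TRUE`); at least
#'   3 observations each.
#' @param paired Logical.
#' @param alpha Gate level for the normality tests.
#' @param method `"auto"` (gate decides), or force `"parametric"` /
#'   `"nonparametric"`.
#' @return A list of class `gated_test` with `test` (name of the test
#'   actually run), `statistic`, `p_value`, `normal` (logical per sample),
#'   `normality_p`, and `summaries` (mean, sd, median, IQR per sample).
#' @examples
#' gated_compare(rnorm(20), rnorm(20) + 1)
#' @export
gated_compare <- function(a, b, paired = FALSE, alpha = 0.05,
                          method = c("auto", "parametric",
                                     "nonparametric")) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3 || length(b) < 3)
    stop("need at least 3 observations per sample", call. = FALSE)
  if (paired && length(a) != length(b))
    stop("paired samples must have equal length", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (!isTRUE(all.equal(mean(a), mean(b))))
      stop("both samples have zero variance with different means: ",
           "no test applies", call. = FALSE)
    res <- list(test = "degenerate (identical constants)", statistic = 0,
                p_value = 1)
  } else if (paired && all(a - b == 0)) {
    # identical paired samples: zero difference with certainty
    res <- list(test = "paired t test (degenerate zero difference)",
                statistic = 0, p_value = 1)
  } else {
    pa <- ks_normal_p(a); pb <- ks_normal_p(b)
    normal <- c(pa, pb) > alpha
    use_t <- switch(method, auto = all(normal), parametric = TRUE,
                    nonparametric = FALSE)
    if (use_t) {
      tt <- stats::t.test(a, b, paired = paired)
      res <- list(test = if (paired) "paired t test" else "unpaired t test",
                  statistic = unname(tt$statistic), p_value = tt$p.value)
    } else if (paired) {
      wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
      res <- list(test = "Wilcoxon signed-rank test",
                  statistic = unname(wt$statistic), p_value = wt$p.value)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(a, b))
      res <- list(test = "Mann-Whitney U test",
                  statistic = unname(wt$statistic), p_value = wt$p.value)
    }
    res$normality_p <- c(a = pa, b = pb)
    res$normal <- normal
  }
  res$summaries <- data.frame(
    sample = c("a", "b"),
    n = c(length(a), length(b)),
    mean = c(mean(a), mean(b)), sd = c(stats::sd(a), stats::sd(b)),
    median = c(stats::median(a), stats::median(b)),
    iqr = c(stats::IQR(a), stats::IQR(b)))
  class(res) <- "gated_test"
  res
}

#' @export
print.gated_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n",
              x$test, x$statistic, x$p_value))
  print(x$summaries, row.names = FALSE)
  invisible(x)
}

#' Univariate linear regression
#'
#' Ordinary least squares of `y` on a single predictor, reported the way a
#' clinical univariate screen is tabulated: coefficient, standard error,
#' t-based 95% confidence interval, p-value, and model R-squared.
#'
#' @param y Numeric outcome.
#' @param x Single predictor (numeric, logical, or 2-level factor).
#' @param conf_level Confidence level for the interval.
#' @return A list of class `uni_ols` with `coefficient`, `se`, `ci`
#'   (length 2), `p_value`, `r_squared`, `n`, and the underlying `lm` fit.
#' @export
univariate_ols <- function(y, x, conf_level = 0.95) {
  if (is.factor(x) || is.character(x)) x <- as.numeric(factor(x)) - 1
  x <- as.numeric(x); y <- as.numeric(y)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(y) <= 2) stop("need n > 2", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant predictor: singular fit",
                              call. = FALSE)
  fit <- stats::lm(y ~ x)
  # summary.lm warns on an exactly collinear response; the SE/CI of 0 it
  # returns are still the right answer for that degenerate case
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients["x", ]
  ci <- suppressWarnings(stats::confint(fit, "x", level = conf_level))
  structure(list(coefficient = unname(co["Estimate"]),
                 se = unname(co["Std. Error"]),
                 ci = as.numeric(ci),
                 p_value = unname(co["Pr(>|t|)"]),
                 r_squared = sm$r.squared, n = length(y), fit = fit),
            class = "uni_ols")
}

#' @export
print.uni_ols <- function(x, ...) {
  cat(sprintf("coef %.6g (SE %.4g), 95%% CI %.6g to %.6g, p = %.3g, R^2 = %.4f\n",
              x$coefficient, x$se, x$ci[1], x$ci[2], x$p_value, x$r_squared))
  invisible(x)
}

#' Stepwise multiple linear regression with p-value entry/removal
#'
#' Forward selection with backward elimination driven by partial t-test
#' p-values: at each step the candidate with the smallest p-value below
#' `p_enter` (ties broken by input order) is added, then any included
#' variable whose partial p-value exceeds `p_remove` is dropped (largest
#' first).  Iterates to a fixed point and returns the final model plus an
#' audit log of every enter/remove decision.
#'
#' @param y Numeric outcome.
#' @param X Data frame of candidate predictors (numeric/logical/2-level
#'   factors).
#' @param p_enter Entry threshold (default 0.05).
#' @param p_remove Removal threshold (default 0.1).
#' @return A list of class `stepwise_ols` with `selected` (character),
#'   `coefficients` (data frame: term, coefficient, se, ci_low, ci_high,
#'   p_value), `r_squared`, `steps` (audit log data frame), and `fit`
#'   (`lm` or `NULL` for the empty model).
#' @export
stepwise_ols <- function(y, X, p_enter = 0.05, p_remove = 0.1) {
  stopifnot(is.data.frame(X))
  Xn <- as.data.frame(lapply(X, function(v) {
    if (is.factor(v) || is.character(v)) as.numeric(factor(v)) - 1
    else as.numeric(v)
  }))
  y <- as.numeric(y)
  included <- character(0)
  steps <- list()
  log_step <- function(action, term, p)
    steps[[length(steps) + 1L]] <<-
      data.frame(step = length(steps) + 1L, action = action,
                 term = term, p_value = p)
  partial_p <- function(vars) {
    fit <- stats::lm(y ~ ., data = Xn[, vars, drop = FALSE])
    sm <- summary(fit)$coefficients
    sm[match(vars, rownames(sm)), "Pr(>|t|)"]
  }
  repeat {
    changed <- FALSE
    # forward step: best candidate below p_enter
    cand <- setdiff(names(Xn), included)
    if (length(cand)) {
      pc <- vapply(cand, function(v) partial_p(c(included, v))[
        length(included) + 1L], numeric(1))
      if (any(pc < p_enter, na.rm = TRUE)) {
        best <- cand[which.min(pc)]  # smallest p, first in input order on ties
        included <- c(included, best)
        log_step("enter", best, min(pc, na.rm = TRUE))
        changed <- TRUE
      }
    }
    # backward step: drop anything above p_remove
    repeat {
      if (length(included) == 0L) break
      pp <- partial_p(included)
      if (all(pp <= p_remove, na.rm = TRUE)) break
      worst <- included[which.max(pp)]
      log_step("remove", worst, max(pp, na.rm = TRUE))
      included <- setdiff(included, worst)
      changed <- TRUE
    }
    if (!changed) break
  }
  if (length(included) == 0L) {
    out <- list(selected = character(0),
                coefficients = data.frame(term = character(0),
                                          coefficient = numeric(0),
                                          se = numeric(0), ci_low = numeric(0),
                                          ci_high = numeric(0),
                                          p_value = numeric(0)),
                r_squared = 0,
                steps = if (length(steps)) do.call(rbind, steps)
                        else data.frame(step = integer(0),
                                        action = character(0),
                                        term = character(0),
                                        p_value = numeric(0)),
                fit = NULL)
  } else {
    fit <- stats::lm(y ~ ., data = Xn[, included, drop = FALSE])
    sm <- summary(fit)$coefficients
    ci <- stats::confint(fit)
    rows <- match(included, rownames(sm))
    out <- list(
      selected = included,
      coefficients = data.frame(term = included,
                                coefficient = sm[rows, "Estimate"],
                                se = sm[rows, "Std. Error"],
                                ci_low = ci[rows, 1], ci_high = ci[rows, 2],
                                p_value = sm[rows, "Pr(>|t|)"],
                                row.names = NULL),
      r_squared = summary(fit)$r.squared,
      steps = do.call(rbind, steps), fit = fit)
  }
  class(out) <- "stepwise_ols"
  out
}

#' @export
print.stepwise_ols <- function(x, ...) {
  if (length(x$selected) == 0L) {
    cat("Stepwise OLS: empty model (no candidate met the entry threshold); ",
        "R^2 = 0\n", sep = "")
  } else {
    cat(sprintf("Stepwise OLS: selected %s; R^2 = %.4f\n",
                paste(x$selected, collapse = ", "), x$r_squared))
    print(x$coefficients, row.names = FALSE)
  }
  invisible(x)
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation for two (or more) raters measuring the same subjects,
#' computed from the two-way ANOVA mean squares:
#' \deqn{ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E + k (MS_C - MS_E)/n)}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the row (subject), column
#' (rater) and error mean squares.
#'
#' @param obs1,obs2 Paired measurements (first/second observer), or `obs1`
#'   may be a subjects x raters matrix with `obs2` missing.
#' @return List of class `icc_result` with `icc`, `ms` (mean squares), `n`,
#'   `k`, and `form = "ICC(2,1)"`.
#' @export
icc <- function(obs1, obs2 = NULL) {
  m <- if (is.null(obs2)) as.matrix(obs1) else cbind(obs1, obs2)
  if (any(!is.finite(m))) stop("non-finite measurements", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  if (ss_tot == 0)
    stop("zero total variance: ICC undefined", call. = FALSE)
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  val <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  structure(list(icc = val, ms = c(MSR = msr, MSC = msc, MSE = mse),
                 n = n, k = k, form = "ICC(2,1)"),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("%s (two-way random, absolute agreement, single measures): %.4f\n",
              x$form, x$icc))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Mean inter-observer difference and 95% limits of agreement
#' (mean difference +/- 1.96 SD of the differences), plus the coefficient of
#' variation defined as the SD of the within-pair differences divided by the
#' grand mean, in percent.
#'
#' @param obs1,obs2 Paired measurements.
#' @return List of class `bland_altman` with `mean_diff`, `sd_diff`,
#'   `limits` (lower, upper), `cv_percent`, and the per-pair `means` and
#'   `differences`.
#' @export
bland_altman <- function(obs1, obs2) {
  stopifnot(length(obs1) == length(obs2), length(obs1) >= 2)
  d <- obs1 - obs2
  md <- mean(d); sdd <- stats::sd(d)
  grand <- mean(c(obs1, obs2))
  structure(list(mean_diff = md, sd_diff = sdd,
                 limits = c(lower = md - 1.96 * sdd,
                            upper = md + 1.96 * sdd),
                 cv_percent = if (grand != 0) 100 * sdd / grand else NA_real_,
                 means = (obs1 + obs2) / 2, differences = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean difference %.4g, limits of agreement %.4g to %.4g, CV %.2f%%\n",
              x$mean_diff, x$limits[1], x$limits[2], x$cv_percent))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$differences, xlab = "mean of observers",
                 ylab = "difference", ...)
  graphics::abline(h = c(x$mean_diff, x$limits), lty = c(1, 2, 2))
  invisible(x)
}

#' Pearson chi-squared test on a contingency table
#'
#' Pearson chi-squared statistic without continuity correction; a warning
#' is recorded when any expected cell count is below 1.
#'
#' @param tab A matrix of counts.
#' @return List of class `gated_test` (name, statistic, p-value) with the
#'   expected counts attached.
#' @export
chi_squared_test <- function(tab) {
  tab <- as.matrix(tab)
  if (sum(tab) == 0) stop("empty table", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  low <- any(ct$expected < 1)
  if (low) warning("expected cell count below 1; chi-squared approximation ",
                   "unreliable", call. = FALSE)
  structure(list(test = "Pearson chi-squared (no continuity correction)",
                 statistic = unname(ct$statistic),
                 p_value = ct$p.value, expected = ct$expected,
                 low_expected = low,
                 summaries = as.data.frame.matrix(tab)),
            class = "gated_test")
}
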