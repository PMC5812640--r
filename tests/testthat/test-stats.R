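test_that("gated comparison handles identity and degenerate input", {
  x <- c(1.2, 1.5, 1.9, 2.2, 2.8, 3.1)
  res <- gated_compare(x, x, paired = TRUE)
  expect_equal(res$p_value, 1)
  expect_equal(res$statistic, 0)
  expect_error(gated_compare(c(1, 1, 1), c(2, 2, 2)), "zero variance")
  expect_error(gated_compare(1:2, 1:5), "at least 3")
})

test_that("the gate decides between t and rank tests and is recorded", {
  set.seed(202)
  a <- rnorm(30); b <- rnorm(30, 1)
  res <- gated_compare(a, b)
  expect_true(all(res$normal))
  expect_match(res$test, "t test")
  expect_equal(res$p_value, stats::t.test(a, b)$p.value)

  skewed <- exp(rnorm(40, 0, 1.5))
  other <- rnorm(40, 2)
  res2 <- gated_compare(skewed, other)
  expect_false(all(res2$normal))
  expect_match(res2$test, "Mann-Whitney")
  expect_equal(res2$p_value,
               suppressWarnings(stats::wilcox.test(skewed, other)$p.value))

  # paired non-normal data goes to the signed-rank test
  res3 <- gated_compare(skewed, skewed * exp(rnorm(40, 0.2, 0.5)),
                        paired = TRUE)
  expect_match(res3$test, "signed-rank")
})

test_that("Mann-Whitney p matches exhaustive enumeration for small groups", {
  cases <- list(
    list(a = c(1, 2, 3), b = c(4, 5, 6)),
    list(a = c(1.3, 2.2, 5.1, 6.0), b = c(0.4, 3.3, 4.1)),
    list(a = c(10, 12, 13, 15, 19), b = c(11, 14, 16, 17, 18, 20)),
    list(a = c(0.1, 0.9, 2.5, 7.2, 8.8, 9.1, 9.9),
         b = c(0.5, 1.1, 3.3, 4.4, 6.6))
  )
  for (cs in cases) {
    got <- gated_compare(cs$a, cs$b, method = "nonparametric")$p_value
    expect_equal(got, mw_exact_p(cs$a, cs$b), tolerance = 1e-12)
  }
})

test_that("univariate OLS matches the normal equations", {
  # perfect fit
  x <- 1:10
  u <- univariate_ols(2 * x, x)
  expect_equal(u$coefficient, 2, tolerance = 1e-12)
  expect_equal(u$se, 0, tolerance = 1e-10)
  expect_equal(u$r_squared, 1, tolerance = 1e-12)
  expect_error(univariate_ols(rnorm(10), rep(1, 10)), "singular|constant")

  # random small designs against the closed form
  set.seed(9)
  for (i in 1:5) {
    n <- sample(5:30, 1)
    xx <- rnorm(n); yy <- 1 + 0.7 * xx + rnorm(n)
    u <- univariate_ols(yy, xx)
    beta <- sum((xx - mean(xx)) * (yy - mean(yy))) / sum((xx - mean(xx))^2)
    resid <- yy - mean(yy) - beta * (xx - mean(xx))
    se <- sqrt(sum(resid^2) / (n - 2) / sum((xx - mean(xx))^2))
    expect_equal(u$coefficient, beta, tolerance = 1e-10)
    expect_equal(u$se, se, tolerance = 1e-10)
    expect_equal(u$p_value, 2 * stats::pt(-abs(beta / se), n - 2),
                 tolerance = 1e-10)
    # CI brackets the coefficient
    expect_lt(u$ci[1], u$coefficient); expect_gt(u$ci[2], u$coefficient)
  }
  # coefficient within its own CI of the true value for a strong signal
  set.seed(10)
  xx <- rnorm(100); yy <- xx + rnorm(100)
  u <- univariate_ols(yy, xx)
  expect_true(u$ci[1] <= 1 && 1 <= u$ci[2])
})

test_that("stepwise selection recovers a strong predictor and stays empty under the null", {
  set.seed(21)
  member <- 0; alone <- 0; nulls <- 0; reps <- 20
  for (i in seq_len(reps)) {
    n <- 44
    x_true <- rep(0:1, length.out = n)
    X <- data.frame(x_true = x_true,
                    n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
                    n4 = rnorm(n), n5 = rnorm(n), n6 = rnorm(n))
    y <- 1.5 * x_true + rnorm(n)
    sw <- stepwise_ols(y, X)
    if ("x_true" %in% sw$selected) member <- member + 1
    if (identical(sw$selected, "x_true")) alone <- alone + 1
    y0 <- rnorm(n)
    sw0 <- stepwise_ols(y0, X)
    if (length(sw0$selected) == 0L) nulls <- nulls + 1
  }
  # a 1.5-SD effect is essentially always detected; noise covariates may
  # occasionally slip in (each has a ~5% entry chance per model)
  expect_equal(member, reps)
  expect_gte(alone / reps, 0.5)
  expect_gte(nulls / reps, 0.5) # ~ (1 - 0.05)^7 under independence
})

test_that("stepwise audit log replays to the final model", {
  set.seed(33)
  n <- 60
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- 2 * X$a - 1.5 * X$b + rnorm(n)
  sw <- stepwise_ols(y, X)
  replayed <- character(0)
  for (i in seq_len(nrow(sw$steps))) {
    st <- sw$steps[i, ]
    replayed <- if (st$action == "enter") c(replayed, st$term)
                else setdiff(replayed, st$term)
  }
  expect_setequal(replayed, sw$selected)
  expect_gte(sw$r_squared, 0); expect_lte(sw$r_squared, 1)
  # empty-model contract
  sw0 <- stepwise_ols(rnorm(20), data.frame(z = rnorm(20)))
  if (length(sw0$selected) == 0L) expect_equal(sw0$r_squared, 0)
})

test_that("ICC(2,1) matches a hand-computed ANOVA table and its identities", {
  expect_equal(icc(c(1, 2, 3, 4), c(1, 2, 3, 4))$icc, 1)

  # hand computation, n = 4 subjects, k = 2 raters, constant shift 0.4:
  # rows (1,1.4) (2,2.4) (3,3.4) (4,4.4); grand mean 2.7
  # SSrows = 2*((1.2-2.7)^2+(2.2-2.7)^2+(3.2-2.7)^2+(4.2-2.7)^2) = 10
  # SScols = 4*((2.5-2.7)^2+(2.9-2.7)^2) = 0.32, SSerr = 0
  # MSR = 10/3, MSC = 0.32, MSE = 0
  # ICC = (10/3) / (10/3 + 2*(0.32 - 0)/4) = (10/3)/(10/3 + 0.16)
  o1 <- c(1, 2, 3, 4); o2 <- o1 + 0.4
  expect_equal(icc(o1, o2)$icc, (10 / 3) / (10 / 3 + 0.16),
               tolerance = 1e-12)
  expect_lt(icc(o1, o2)$icc, 1)

  set.seed(8)
  noise <- icc(rnorm(1000), rnorm(1000))
  expect_lt(abs(noise$icc), 0.1)
  expect_error(icc(rep(1, 5), rep(1, 5)), "zero total variance")
})

test_that("Bland-Altman limits and CV follow the hand arithmetic", {
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mean_diff, 0)
  expect_equal(unname(diff(same$limits)), 0)

  ba <- bland_altman(c(1, 3), c(2, 2)) # differences -1, +1
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, sqrt(2))
  expect_equal(unname(ba$limits), c(-1.96 * sqrt(2), 1.96 * sqrt(2)))

  # CV = 100 * sd(differences) / grand mean on 3 pairs
  o1 <- c(0.8, 0.9, 1.0); o2 <- c(0.82, 0.88, 1.04)
  ba3 <- bland_altman(o1, o2)
  expect_equal(ba3$cv_percent, 100 * sd(o1 - o2) / mean(c(o1, o2)),
               tolerance = 1e-12)
})

test_that("MDRD eGFR evaluates and scales as a power law", {
  expect_equal(egfr_mdrd(1.0, 50, female = FALSE), 79.0946553183,
               tolerance = 1e-9)
  base <- egfr_mdrd(0.9, 61)
  expect_equal(egfr_mdrd(1.8, 61), base * 2^(-1.154), tolerance = 1e-12)
  expect_equal(egfr_mdrd(0.9, 61, female = TRUE), base * 0.742)
  expect_equal(egfr_mdrd(0.9, 61, black = TRUE), base * 1.212)
  expect_error(egfr_mdrd(0, 50), "positive")
  expect_error(egfr_mdrd(1, -2), "positive")
})

test_that("hepatic thresholds are strict", {
  expect_equal(hepatic_flag(40, 40, 63, 1.2), "normal")
  expect_equal(hepatic_flag(41, 0, 0, 0), "abnormal")
  expect_equal(hepatic_flag(0, 0, 0, 1.3), "abnormal")
  expect_equal(hepatic_flag(c(40, 41), c(40, 0), c(63, 0), c(1.2, 0)),
               c("normal", "abnormal"))
})

test_that("chi-squared statistic matches hand computation", {
  same <- chi_squared_test(rbind(c(5, 10), c(5, 10)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  diag <- chi_squared_test(rbind(c(10, 0), c(0, 10)))
  expect_equal(diag$statistic, 20)
  expect_warning(chi_squared_test(rbind(c(1, 0), c(0, 1))), "below 1")
})
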