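# reliability and validity statistics

test_that("Bland-Altman bias and limits match hand computation", {
  ba <- bland_altman(c(1, 2, 3), c(2, 4, 6))
  expect_equal(ba$bias, -2)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_upper, -0.04)
  expect_equal(ba$loa_lower, -3.96)
  expect_equal(ba$loa_upper - ba$loa_lower, 2 * 1.96 * ba$sd_diff)

  same <- bland_altman(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$bias, 0)
  expect_equal(c(same$loa_lower, same$loa_upper), c(0, 0))

  shift <- bland_altman(c(3, 4, 5), c(1, 2, 3))
  expect_equal(shift$bias, 2)
  expect_equal(shift$sd_diff, 0)
  expect_equal(c(shift$loa_lower, shift$loa_upper), c(2, 2))

  expect_error(bland_altman(1:2, 1:2), class = "anthroval_input_error")
})

test_that("swapping methods negates the bias and mirrors the limits", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      x <- rnorm(15, 10, 2)
      y <- rnorm(15, 11, 2)
      ab <- bland_altman(x, y)
      ba <- bland_altman(y, x)
      expect_equal(ba$bias, -ab$bias)
      expect_equal(ba$loa_lower, -ab$loa_upper)
      expect_equal(ba$loa_upper, -ab$loa_lower)
    }
  })
})

test_that("typical-error CV matches its pairwise definition", {
  one <- typical_error_cv(9, 11)
  expect_equal(one$cv_mean, 100 * (2 / sqrt(2)) / 10, tolerance = 1e-12)

  ident <- typical_error_cv(c(4, 5, 6), c(4, 5, 6))
  expect_equal(ident$cv_mean, 0)
  expect_equal(ident$cv_sd, 0)

  # scale invariance under common positive rescaling
  withr::with_seed(8, {
    x <- runif(12, 5, 15)
    y <- runif(12, 5, 15)
    a <- typical_error_cv(x, y)
    b <- typical_error_cv(3.7 * x, 3.7 * y)
    expect_equal(a$cv, b$cv, tolerance = 1e-12)
  })
  expect_error(typical_error_cv(c(1, -3), c(1, 1)),
               class = "anthroval_domain_error")
})

test_that("TEM follows sqrt(sum d^2 / 2n) with %TEM on the grand mean", {
  t1 <- tem(c(10, 20), c(11, 21))
  expect_equal(t1$tem_abs, sqrt(2 / 4))
  expect_equal(t1$tem_percent, 100 * sqrt(0.5) / 15.5)
  expect_true(t1$pass)

  expect_equal(tem(c(3, 4, 5), c(3, 4, 5))$tem_abs, 0)

  # doubling all measurements doubles TEM but leaves %TEM unchanged
  withr::with_seed(9, {
    a <- runif(10, 5, 20)
    b <- a + rnorm(10, 0, 0.5)
    t_a <- tem(a, b)
    t_2a <- tem(2 * a, 2 * b)
    expect_equal(t_2a$tem_abs, 2 * t_a$tem_abs, tolerance = 1e-12)
    expect_equal(t_2a$tem_percent, t_a$tem_percent, tolerance = 1e-12)
  })
})

test_that("ICC(A,1) matches hand ANOVA and the brute-force oracle", {
  # column 2 = column 1 + 1: MSR = 10/3, MSC = 2, MSE = 0 -> 10/13
  expect_equal(icc_a1(cbind(1:4, 2:5)), 10 / 13, tolerance = 1e-12)
  # identical columns with subject variance: perfect agreement
  expect_equal(icc_a1(cbind(c(1, 5, 9), c(1, 5, 9))), 1)
  # permuting subjects changes nothing
  m <- cbind(c(3, 7, 2, 9), c(4, 6, 1, 8))
  expect_equal(icc_a1(m), icc_a1(m[c(4, 2, 1, 3), ]))
  # zero total variance: 1 by convention, with a message
  expect_message(v <- icc_a1(matrix(2, 4, 2)), "convention")
  expect_equal(v, 1)

  withr::with_seed(123, {
    for (rep in 1:50) {
      n <- sample(5:30, 1)
      m <- cbind(rnorm(n, 10, 3), rnorm(n, 10, 3))
      expect_equal(icc_a1(m), icc_oracle(m), tolerance = 1e-10)
    }
  })
})

test_that("percent difference is absolute with the reference underneath", {
  expect_equal(percent_diff(11, 10)$mean, 10)
  expect_equal(percent_diff(9, 10)$mean, 10)   # absolute value
  both <- percent_diff(c(4, 5, 6), c(4, 5, 6))
  expect_equal(both$mean, 0)
  expect_equal(both$sd, 0)
  expect_error(percent_diff(5, 0), class = "anthroval_domain_error")
})

test_that("Cohen's d uses the pooled two-column SD and upward bands", {
  # means 10 and 11, both SDs exactly 2 -> d = 0.5, medium
  d <- cohens_d(c(8, 10, 12), c(9, 11, 13))
  expect_equal(d$d, 0.5)
  expect_equal(d$band, "medium")

  same <- cohens_d(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$d, 0)
  expect_equal(same$band, "trivial")

  # symmetry under method swap
  withr::with_seed(55, {
    x <- rnorm(20, 10, 2)
    y <- rnorm(20, 12, 3)
    expect_equal(cohens_d(x, y)$d, cohens_d(y, x)$d)
  })

  expect_equal(es_band(c(0.1, 0.2, 0.5, 0.8, 2)),
               c("trivial", "small", "medium", "large", "large"))
  expect_equal(es_band(0.8), "large")

  inf <- cohens_d(c(2, 2, 2), c(3, 3, 3))
  expect_true(inf$infinite)
})

test_that("location test routes on Shapiro-Wilk and matches closed forms", {
  withr::with_seed(61, {
    y <- rnorm(25, 70, 5)
    shift <- rnorm(25, 2, 1)
    x <- y + shift
    res <- paired_location_test(x, y)
    expect_equal(res$test, "paired_t")
    # closed-form paired t on the differences
    expect_equal(res$statistic, mean(shift) / (sd(shift) / sqrt(25)),
                 tolerance = 1e-12)

    # strongly skewed differences fail the gate
    y2 <- rnorm(30, 70, 5)
    x2 <- y2 + rlnorm(30, 0, 1.2)
    res2 <- paired_location_test(x2, y2)
    expect_equal(res2$test, "wilcoxon")
    # p agrees with the uncorrected normal-approximation reference
    ref <- suppressWarnings(
      wilcox.test(x2, y2, paired = TRUE, exact = FALSE,
                  correct = FALSE))
    expect_equal(res2$p, ref$p.value, tolerance = 1e-10)
    # systematic overestimation gives a positive Z here
    expect_gt(res2$statistic, 0)
  })

  degen <- paired_location_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(degen$test, "degenerate")
  expect_equal(degen$p, 1)
})

test_that("verdict applies inclusive CV and ICC thresholds", {
  expect_equal(verdict(0.858, 8.8), "acceptable")
  expect_equal(verdict(0.793, 12.6), "unacceptable")
  expect_equal(verdict(0.8, 10.0), "acceptable")    # both boundaries
  expect_equal(verdict(0.799, 5), "unacceptable")
  expect_equal(verdict(0.95, 10.01), "unacceptable")
  # overridable thresholds
  expect_equal(verdict(0.9, 5, icc_threshold = 0.95), "unacceptable")
})

test_that("lean-mass-on-maturity regression matches normal equations", {
  reg <- lm_maturity_regression(c(60, 66, 69, 75), c(1, 2, 3, 4))
  expect_equal(reg$slope, 4.8)
  expect_equal(reg$r2, 115.2 / 117, tolerance = 1e-10)
  expect_equal(reg$r2_adj, 1 - (1 - 115.2 / 117) * 3 / 2,
               tolerance = 1e-10)
  expect_equal(reg$f, 128, tolerance = 1e-8)
  expect_equal(c(reg$df1, reg$df2), c(1, 2))
  expect_lte(reg$r2_adj, reg$r2)

  # translation of the response moves only the intercept
  reg2 <- lm_maturity_regression(c(60, 66, 69, 75) + 10, c(1, 2, 3, 4))
  expect_equal(reg2$slope, reg$slope)
  expect_equal(reg2$intercept, reg$intercept + 10)

  # collinear data: perfect fit (summary.lm warns about it, expectedly)
  reg3 <- suppressWarnings(lm_maturity_regression(2 * (1:5) + 3, 1:5))
  expect_equal(reg3$r2, 1, tolerance = 1e-12)

  expect_error(lm_maturity_regression(c(60, 61, 62), c(2, 2, 2)),
               class = "anthroval_input_error")
})

test_that("paired-t power has correct limits and matches simulation", {
  expect_gt(power_paired_t(5, 25), 0.999999)
  expect_lt(power_paired_t(0.5, 25, alpha = 1e-10), 0.01)
  # exact noncentral-t power vs 100,000-rep Monte-Carlo at d = 0.78
  d <- 0.78
  n <- 25
  reps <- 100000
  withr::with_seed(2024, {
    draws <- matrix(rnorm(n * reps, mean = d, sd = 1), nrow = n)
    means <- colMeans(draws)
    sds <- sqrt(colMeans(draws^2) * n / (n - 1) -
                  means^2 * n / (n - 1))
    tstat <- means / (sds / sqrt(n))
    mc_power <- mean(abs(tstat) > qt(0.975, n - 1))
  })
  expect_equal(power_paired_t(d, n), mc_power, tolerance = 0.005)
})

test_that("agreement_report bundles consistent statistics", {
  withr::with_seed(303, {
    y <- rnorm(25, 10, 2)
    x <- y + rnorm(25, 1, 0.8)
    rep <- agreement_report(x, y, equation = "demo", outcome = "fm")
  })
  expect_equal(nrow(rep), 1)
  expect_equal(rep$loa_upper - rep$loa_lower, 2 * 1.96 * rep$sd_diff)
  expect_equal(rep$verdict, verdict(rep$icc, rep$cv_mean))
  expect_equal(rep$n, 25)
  expect_true(rep$test %in% c("paired_t", "wilcoxon"))
})
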