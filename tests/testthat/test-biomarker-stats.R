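test_that("VSRAD Z-score matches its defining endpoints", {
  expect_equal(vsrad_z(5, 5, 2), 0)
  expect_equal(vsrad_z(3, 5, 2), 1)    # one SD below control mean
  expect_equal(vsrad_z(9, 5, 2), -2)   # two SDs above
  expect_error(vsrad_z(1, 0, 0), "positive")
})

test_that("normalization equations hit their printed endpoints", {
  coh <- data.frame(id = 1:4, group = c("CN", "CN", "AD", "AD"),
                    centiloid = c(0, 10, 60, 90),
                    MMSE = c(30, 0, 20, 10),
                    VSRAD = c(0.5, 2.5, 1.0, 2.0),
                    ALPS_b1000 = c(1.6, 1.0, 1.3, 1.2))
  norm <- normalize_biomarkers(coh)
  k <- attr(norm, "constants")
  expect_equal(k$ALPS_MAX, 1.6)
  expect_equal(norm$nMMSE, c(0, 100, 100 / 3, 200 / 3))
  expect_equal(norm$nDTI_ALPS[1], 0)     # ALPS = ALPS_MAX
  expect_equal(norm$nDTI_ALPS[2], 100)   # ALPS = 1
  expect_equal(norm$nVSRAD[1], 0)        # VSRAD = VSRAD_MIN
  # printed denominator is VSRAD_MAX, not the range
  expect_equal(norm$nVSRAD[2], (2.5 - 0.5) / 2.5 * 100)
  norm_r <- normalize_biomarkers(coh, vsrad_denominator = "range")
  expect_equal(norm_r$nVSRAD[2], 100)
  coh$ALPS_b1000 <- coh$ALPS_b1000 - 0.7
  expect_error(normalize_biomarkers(coh), "ALPS_MAX")
})

test_that("normalization is affine and preserves correlation magnitude", {
  coh <- simulate_cohort(cohort_spec(), seed = 12, verbose = FALSE)
  norm <- normalize_biomarkers(coh)
  expect_equal(abs(cor(norm$nMMSE, coh$centiloid)),
               abs(cor(coh$MMSE, coh$centiloid)), tolerance = 1e-12)
  expect_equal(abs(cor(norm$nDTI_ALPS, coh$centiloid)),
               abs(cor(coh$ALPS_b1000, coh$centiloid)), tolerance = 1e-12)
  # chain rule: normalized slope = raw slope * -100/(ALPS_MAX - 1)
  k <- attr(norm, "constants")
  raw <- pearson_regression(coh$centiloid, coh$ALPS_b1000)
  nrm <- pearson_regression(norm$centiloid, norm$nDTI_ALPS)
  expect_equal(nrm$slope, raw$slope * (-100 / (k$ALPS_MAX - 1)),
               tolerance = 1e-10)
})

test_that("pearson_regression matches closed-form covariance arithmetic", {
  withr::with_seed(33, {
    for (i in 1:100) {
      n <- sample(5:30, 1)
      x <- rnorm(n); y <- 0.5 * x + rnorm(n)
      got <- pearson_regression(x, y)
      want <- closed_form_regression(x, y)
      expect_equal(got$slope, want$slope, tolerance = 1e-12)
      expect_equal(got$intercept, want$intercept, tolerance = 1e-12)
      expect_equal(got$r, want$r, tolerance = 1e-12)
      expect_equal(got$p, want$p, tolerance = 1e-12)
    }
  })
})

test_that("exact linear data give slope 2, intercept 1, r = 1", {
  x <- 1:5
  fit <- pearson_regression(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r, 1)
  expect_error(pearson_regression(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pearson_regression(1:2, 1:2), "at least 3")
})

test_that("independent data yield near-zero r and calibrated p-values", {
  withr::with_seed(91, {
    x <- rnorm(1e4); y <- rnorm(1e4)
    expect_lt(abs(pearson_regression(x, y)$r), 0.05)
    ps <- vapply(1:200, function(i) {
      pearson_regression(rnorm(20), rnorm(20))$p
    }, numeric(1))
  })
  # uniform null p-values: Kolmogorov-Smirnov should not reject strongly
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  withr::with_seed(44, {
    for (i in 1:100) {
      n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
      x1 <- rnorm(n1); x2 <- rnorm(n2, mean = runif(1, -1, 1))
      coh <- data.frame(group = rep(c("a", "b"), c(n1, n2)),
                        v = c(x1, x2))
      gc <- group_compare(coh, "v")
      expect_equal(gc$F, pooled_t(x1, x2)^2, tolerance = 1e-10)
      expect_equal(gc$lsd$p, gc$p, tolerance = 1e-12)  # LSD = ANOVA, k = 2
    }
  })
})

test_that("degenerate group comparisons are handled explicitly", {
  same <- data.frame(group = rep(c("a", "b"), each = 4),
                     v = rep(c(1, 2, 3, 4), 2))
  gc <- group_compare(same, "v")   # identical groups
  expect_equal(gc$F, 0)
  expect_equal(gc$p, 1)
  flat <- data.frame(group = rep(c("a", "b"), each = 3), v = rep(5, 6))
  gc2 <- group_compare(flat, "v")  # zero variance everywhere
  expect_equal(gc2$F, 0)
  expect_equal(gc2$p, 1)
  expect_equal(gc2$lsd$p, 1)
  expect_error(group_compare(data.frame(group = c("a", "a", "b"),
                                        v = 1:3), "v"), "at least 2")
})

test_that("Fisher LSD uses the pooled ANOVA mean square", {
  withr::with_seed(77, {
    coh <- data.frame(group = rep(c("a", "b", "c"), each = 10),
                      v = rnorm(30) + rep(c(0, 0.5, 1), each = 10))
  })
  gc <- group_compare(coh, "v")
  expect_equal(nrow(gc$lsd), 3L)
  fit <- aov(v ~ group, data = coh)
  mse <- anova(fit)$`Mean Sq`[2]
  m <- tapply(coh$v, coh$group, mean)
  t_ab <- (m["a"] - m["b"]) / sqrt(mse * (1 / 10 + 1 / 10))
  expect_equal(gc$lsd$t[gc$lsd$pair == "a - b"], unname(t_ab),
               tolerance = 1e-12)
  expect_equal(gc$lsd$p[gc$lsd$pair == "a - b"],
               unname(2 * pt(-abs(t_ab), 27)), tolerance = 1e-12)
})

test_that("sex ratios are compared with a Pearson chi-square test", {
  coh <- simulate_cohort(cohort_spec(), seed = 9, verbose = FALSE)
  ct <- group_compare_categorical(coh, "sex")
  want <- suppressWarnings(chisq.test(table(coh$group, coh$sex),
                                      correct = FALSE))
  expect_equal(ct$statistic, unname(want$statistic))
  expect_equal(ct$p, want$p.value)
  expect_equal(ct$df, 1)
})

test_that("group summary and regression tables carry the headline stats", {
  coh <- simulate_cohort(cohort_spec(), seed = 14, verbose = FALSE)
  t1 <- group_summary_table(coh)
  expect_true(all(c("M:F", "MMSE", "centiloid", "ALPS_b1000") %in%
                    t1$variable))
  expect_equal(t1$p[t1$variable == "ALPS_b1000"],
               group_compare(coh, "ALPS_b1000")$p)
  t2 <- regression_table(coh)
  expect_equal(nrow(t2), 6L)
  row <- t2[t2$predictor == "centiloid" & t2$response == "ALPS_b1000", ]
  direct <- pearson_regression(coh$centiloid, coh$ALPS_b1000)
  expect_equal(row$slope, direct$slope)
  expect_equal(row$r, direct$r)
})

test_that("empirical ANOVA rejection rate matches the noncentral-F oracle", {
  spec <- cohort_spec()
  rate <- mean(vapply(1:300, function(s) {
    coh <- simulate_cohort(spec, seed = 5000 + s, verbose = FALSE)
    group_compare(coh, "ALPS_b1000")$p < 1e-5
  }, logical(1)))
  oracle <- anova_power_oracle(spec, alpha = 1e-5)
  se <- sqrt(oracle * (1 - oracle) / 300)
  expect_lt(abs(rate - oracle), 4 * se)
})

test_that("normalized slopes rank the ALPS biomarker above VSRAD", {
  spec <- cohort_spec()
  wins <- vapply(1:100, function(s) {
    ns <- normalized_slope_analysis(
      simulate_cohort(spec, seed = 7000 + s, verbose = FALSE))
    ns$slope[ns$biomarker == "nDTI_ALPS"] >
      ns$slope[ns$biomarker == "nVSRAD"]
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})

test_that("confidence bands widen away from the predictor mean", {
  withr::with_seed(3, {
    x <- rnorm(40); y <- 1 + 0.5 * x + rnorm(40, sd = 0.3)
  })
  fit <- pearson_regression(x, y)
  band <- confidence_band(fit, c(mean(x), mean(x) + 2 * sd(x)))
  width <- band$upr - band$lwr
  expect_lt(width[1], width[2])
  expect_true(all(band$fit > band$lwr & band$fit < band$upr))
})
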