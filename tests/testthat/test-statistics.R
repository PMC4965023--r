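# Statistical battery against closed-form oracles and frozen reference
# values.

test_that("two_sample_t matches the hand-computed Welch formula", {
  r <- two_sample_t(c(1, 5, 3), c(1, 5, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  a <- c(1, 2, 3); b <- c(4, 5, 6)
  r <- two_sample_t(a, b)
  # closed-form Welch oracle
  se <- sqrt(var(a) / 3 + var(b) / 3)
  t_or <- (mean(a) - mean(b)) / se
  df_or <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(r$statistic, t_or, tolerance = 1e-12)
  expect_equal(r$df, df_or, tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pt(-abs(t_or), df_or), tolerance = 1e-12)

  rp <- two_sample_t(a, b, var_equal = TRUE)
  expect_equal(rp$df, 4)
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "zero variance")
  expect_error(two_sample_t(1, c(1, 2)), "n >= 2")
})

test_that("anova_bonferroni: omnibus F, family size, adjusted p-values", {
  set.seed(5)
  same <- rnorm(30)
  r0 <- anova_bonferroni(c(same, same, same), rep(c("a", "b", "c"), each = 30))
  expect_lt(r0$statistic, 1e-20)

  vals <- c(rnorm(30), rnorm(30), rnorm(30) + 5)
  grp <- rep(c("a", "b", "c"), each = 30)
  r <- anova_bonferroni(vals, grp)
  expect_equal(r$family_size, 3)
  expect_lt(r$p_value, 1e-6)
  pw <- r$pairwise
  expect_true(all(pw$p_adjusted >= pw$p_raw))
  expect_true(all(pw$p_adjusted <= 1))
  sig <- pw$p_adjusted < 0.05
  expect_identical(sig, pw$group1 == "c" | pw$group2 == "c")
  expect_error(anova_bonferroni(rnorm(10), rep(c("a", "b"), 5)), "k >= 3")
})

test_that("paired_t matches the closed form on a 4-pair example", {
  expect_equal(paired_t(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  x <- c(1, 2, 3, 4); y <- c(2, 3, 5, 7)
  r <- paired_t(x, y)
  d <- x - y
  t_or <- mean(d) / (sd(d) / 2)
  expect_equal(r$statistic, t_or, tolerance = 1e-12)
  expect_equal(r$df, 3)
  expect_equal(r$p_value, 2 * pt(-abs(t_or), 3), tolerance = 1e-12)
  expect_error(paired_t(1:3, 1:4), "equal length")
  expect_error(paired_t(c(1, 2, 3), c(2, 3, 4)), "differences")
})

test_that("pearson_with_regression reproduces closed-form slope and r", {
  x <- 1:10
  r <- suppressWarnings(pearson_with_regression(x, 2 * x + 3))  # perfect fit
  expect_equal(r$pearson_r, 1)
  expect_equal(suppressWarnings(pearson_with_regression(x, -x))$pearson_r, -1)

  x <- c(1, 2, 4, 6, 9); y <- c(2.1, 3.9, 6.2, 12.0, 15.5)
  r <- pearson_with_regression(x, y)
  slope_or <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  r_or <- slope_or * sd(x) / sd(y)
  expect_equal(r$slope, slope_or, tolerance = 1e-12)
  expect_equal(r$intercept, mean(y) - slope_or * mean(x), tolerance = 1e-12)
  expect_equal(r$pearson_r, r_or, tolerance = 1e-12)
  expect_error(pearson_with_regression(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("icc_2_1 agrees with the mean-squares oracle and reference value", {
  m <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2))
  r <- icc_2_1(m)
  # ANOVA decomposition by hand
  n <- 6; k <- 2
  grand <- mean(m)
  msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  mse <- (sum(sweep(sweep(m, 1, rowMeans(m)), 2, colMeans(m)) + grand)^2)
  sse <- sum((m - outer(rowMeans(m), colMeans(m), "+") + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc_or <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(r$icc, icc_or, tolerance = 1e-12)
  # frozen reference from an independent implementation (pingouin 0.6.1,
  # ICC(A,1) absolute agreement, single random raters)
  expect_equal(r$icc, 0.125654, tolerance = 1e-5)
  expect_true(r$ci[1] <= r$icc && r$icc <= r$ci[2])

  dup <- cbind(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 6))
  expect_equal(icc_2_1(dup)$icc, 1)
  expect_error(icc_2_1(matrix(3, 6, 2)), "constant")
  expect_error(icc_2_1(matrix(rnorm(8), 4, 2)), ">= 5 subjects")
})

test_that("sample_size_two_means evaluates the normal-approximation formula", {
  expect_identical(sample_size_two_means(3.8, 2.5, 2.8, 0.80, 0.05), 73L)
  # doubling sigma quadruples n
  expect_identical(sample_size_two_means(3.8, 2.5, 5.6, 0.80, 0.05), 292L)
  # monotonicity
  expect_lt(sample_size_two_means(3.8, 2.5, 2.8, 0.50, 0.05),
            sample_size_two_means(3.8, 2.5, 2.8, 0.80, 0.05))
  expect_gt(sample_size_two_means(3.8, 2.5, 2.8, 0.80, 0.01),
            sample_size_two_means(3.8, 2.5, 2.8, 0.80, 0.05))
  expect_error(sample_size_two_means(3, 3, 2.8), "differ")
  expect_error(sample_size_two_means(3.8, 2.5, 2.8, power = 1.2), "strictly between")
})

test_that("normality screen reports but the battery never switches tests", {
  r <- ks_normality(rnorm(100))
  expect_true(r$p_value >= 0 && r$p_value <= 1)
  expect_match(r$test, "Kolmogorov")
})

test_that("run_paper_battery produces the documented sections deterministically", {
  ais <- generate_cohort(ais_cohort_config(26, seed = 61))
  ctl <- generate_cohort(control_cohort_config(6, seed = 62))
  tbl <- measure_cohort(c(ais$subjects, ctl$subjects))
  rep1 <- run_paper_battery(tbl)
  expect_s3_class(rep1, "paper_battery")
  expect_true(all(c("thoracic_delta_ap", "lumbar_delta_ap") %in%
                    names(rep1$group_comparisons)))
  expect_true(length(rep1$apical_vs_junctional) == 2)
  expect_true(all(is.finite(rep1$couplings$per_10deg)))
  rep2 <- run_paper_battery(tbl)
  expect_identical(rep1$couplings$per_10deg, rep2$couplings$per_10deg)
  # scoliosis-only table: comparisons degrade gracefully with warnings
  # (one per missing comparison)
  expect_warning(
    expect_warning(run_paper_battery(tbl[tbl$group == "ais", ]), "no control"),
    "no control"
  )
})
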