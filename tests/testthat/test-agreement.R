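test_that("bland_altman matches closed-form formulas on random pairs", {
  set.seed(7)
  for (n in c(2, 6, 25)) {
    a <- rnorm(n, 0.5, 0.2)
    b <- rnorm(n, 0.5, 0.2)
    ba <- bland_altman(a, b)
    d <- a - b
    expect_equal(ba$mean_diff, mean(d), tolerance = 1e-12)
    expect_equal(ba$sd_diff, sqrt(sum((d - mean(d))^2) / (n - 1)), tolerance = 1e-12)
    expect_equal(ba$sem_diff, ba$sd_diff / sqrt(n), tolerance = 1e-12)
    expect_equal(ba$loa_low, mean(d) - 1.96 * ba$sd_diff, tolerance = 1e-12)
    expect_equal(ba$loa_high, mean(d) + 1.96 * ba$sd_diff, tolerance = 1e-12)
    expect_equal(ba$percent_diff, 100 * mean(d) / mean(c(a, b)), tolerance = 1e-12)
    expect_equal(ba$r_squared, ba$pearson_r^2, tolerance = 1e-15)
  }
})

test_that("bland_altman degenerate and antisymmetric cases", {
  a <- c(0.3, 0.5, 0.7)
  expect_warning(ba0 <- bland_altman(a, a), NA)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$sd_diff, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  b <- c(0.2, 0.6, 0.9)
  f <- bland_altman(a, b); r <- bland_altman(b, a)
  expect_equal(f$mean_diff, -r$mean_diff, tolerance = 1e-15)
  expect_equal(f$loa_low, -r$loa_high, tolerance = 1e-15)
  expect_equal(f$loa_high, -r$loa_low, tolerance = 1e-15)
  expect_error(bland_altman(1, 1), "at least 2")
  expect_warning(bland_altman(c(-1, 1), c(1, -1)), "grand mean")
})

test_that("correlation matches stats::cor and stats::lm, with invariances", {
  set.seed(11)
  a <- rnorm(10); b <- 2 * a + 1 + rnorm(10, sd = 0.3)
  ct <- correlation(a, b)
  expect_equal(ct$pearson_r, cor(a, b), tolerance = 1e-12)
  fit <- lm(b ~ a)
  expect_equal(ct$slope, unname(coef(fit)[2]), tolerance = 1e-12)
  expect_equal(ct$intercept, unname(coef(fit)[1]), tolerance = 1e-12)
  # exact linear relation
  exact <- correlation(a, 2 * a + 1)
  expect_equal(exact$pearson_r, 1, tolerance = 1e-12)
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)
  # affine invariance of |r|
  expect_equal(abs(correlation(3 * a - 2, b)$pearson_r), abs(ct$pearson_r),
               tolerance = 1e-12)
  expect_equal(correlation(-a, b)$pearson_r, -ct$pearson_r, tolerance = 1e-12)
  expect_error(correlation(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("paired_t matches stats::t.test and handles degenerate cases", {
  set.seed(3)
  a <- rnorm(8); b <- rnorm(8)
  tt <- paired_t(a, b)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(tt$t_stat, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(tt$p_value, ref$p.value, tolerance = 1e-12)
  # closed form t = mean/(sd/sqrt(n))
  d <- a - b
  expect_equal(tt$t_stat, mean(d) / (sd(d) / sqrt(8)), tolerance = 1e-12)
  # symmetric: identical inputs, symmetric differences
  expect_equal(paired_t(a, a)$t_stat, 0)
  expect_equal(paired_t(a, a)$p_value, 1)
  expect_equal(paired_t(c(1, 0), c(0, 1))$t_stat, 0)  # d = {1, -1}
  # two-sided symmetry under swap
  sw <- paired_t(b, a)
  expect_equal(abs(sw$t_stat), abs(tt$t_stat), tolerance = 1e-12)
  expect_equal(sw$p_value, tt$p_value, tolerance = 1e-12)
  # zero-variance nonzero differences
  expect_warning(deg <- paired_t(c(1, 1), c(0, 0)), "infinite")
  expect_identical(deg$t_stat, Inf)
  expect_identical(deg$p_value, 0)
})

test_that("summarize_metric matches the mean/SEM formulas", {
  set.seed(5)
  x <- rnorm(12, 100, 15)
  sm <- summarize_metric(x)
  expect_equal(sm$mean, mean(x), tolerance = 1e-12)
  expect_equal(sm$sem, sd(x) / sqrt(12), tolerance = 1e-12)
  expect_equal(summarize_metric(rep(4, 5))$sem, 0)
  expect_error(summarize_metric(3), "at least 2")
})

test_that("tidy and glance expose every agreement statistic", {
  ba <- bland_altman(c(0.25, 0.6, 0.92), c(0.3, 0.35, 0.9))
  td <- tidy(ba)
  gl <- glance(ba)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$term, c("mean_diff", "sd_diff", "sem_diff", "loa_low",
                             "loa_high", "percent_diff", "pearson_r",
                             "r_squared", "t_stat", "p_value"))
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$mean_diff, ba$mean_diff)
  expect_equal(td$estimate[td$term == "loa_high"], ba$loa_high)
})
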