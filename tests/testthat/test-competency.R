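test_that("operator RSD delegates to the replicate RSD", {
  reps <- c(99, 100, 101, 100, 100, 100, 99, 101, 100, 100)
  # hand oracle: mean 100, squared deviations sum 4, sample var 4/9
  expect_equal(operator_rsd(reps), sqrt(4 / 9), tolerance = 1e-12)
  expect_equal(round(operator_rsd(reps), 4), 0.6667)
  expect_equal(operator_rsd(list(replicates = rep(5, 10))), 0)
  expect_equal(operator_rsd(10 * reps), operator_rsd(reps),
               tolerance = 1e-12)
})

test_that("paired comparison gates on Shapiro-Wilk normality", {
  set.seed(101)
  pre <- stats::rnorm(20, 4.1, 0.7)
  post <- stats::rnorm(20, 1.8, 0.4)
  res <- paired_compare(pre, post)
  expect_s3_class(res, "paired_test")
  expect_equal(res$test, "paired_t")
  expect_gt(res$normality_p, 0.05)
  expect_equal(res$dof, 19)

  # an extreme outlier in the differences forces the Wilcoxon branch
  post_out <- post
  post_out[1] <- post[1] - 40
  res_w <- paired_compare(pre, post_out)
  expect_lte(res_w$normality_p, 0.05)
  expect_equal(res_w$test, "wilcoxon")
  expect_false(is.na(res_w$mean_diff))   # Hodges-Lehmann surrogate
  # d_z still reported from the raw differences
  d <- pre - post_out
  expect_equal(res_w$dz, mean(d) / stats::sd(d), tolerance = 1e-12)

  expect_error(paired_compare(pre, pre), "degenerate")
  expect_error(paired_compare(1:2, 3:4), "at least 3")
  expect_error(paired_compare(1:5, 1:4), "equal length")
})

test_that("d_z identity holds on the t branch", {
  set.seed(202)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    pre <- stats::rnorm(n, 4, 0.6)
    post <- stats::rnorm(n, 2, 0.4)
    res <- paired_compare(pre, post)
    if (res$test != "paired_t") next
    expect_equal(res$dz, res$statistic / sqrt(n), tolerance = 1e-12)
    expect_equal(res$dz, cohens_dz_from_t(res$statistic, n),
                 tolerance = 1e-12)
  }
})

test_that("d_z from t reproduces the reported effect sizes", {
  expect_equal(round(cohens_dz_from_t(19.26, 20), 2), 4.31)
  expect_equal(round(cohens_dz_from_t(20.94, 20), 2), 4.68)
  expect_equal(cohens_dz_from_t(0, 20), 0)
  expect_error(cohens_dz_from_t(1, 1), ">= 2")
})

test_that("summary-statistic CI matches the closed form from raw data", {
  set.seed(303)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    d <- stats::rnorm(n, 2, 0.5)
    m <- mean(d)
    t_stat <- m / (stats::sd(d) / sqrt(n))
    ci <- mean_ci(m, t_stat, n)
    # independent route: mean +/- t_crit * sd/sqrt(n), no t statistic used
    crit <- stats::qt(0.975, n - 1)
    expect_equal(ci, c(m - crit * stats::sd(d) / sqrt(n),
                       m + crit * stats::sd(d) / sqrt(n)),
                 tolerance = 1e-9)
    # and matches what t.test itself reports
    expect_equal(ci, as.numeric(stats::t.test(d)$conf.int),
                 tolerance = 1e-9)
  }
})

test_that("confidence intervals widen with the confidence level", {
  ci95 <- mean_ci(2.32, 19.26, 20, level = 0.95)
  ci99 <- mean_ci(2.32, 19.26, 20, level = 0.99)
  expect_lt(ci99[1], ci95[1])
  expect_gt(ci99[2], ci95[2])
  expect_equal(round(ci95, 2), c(2.07, 2.57))
  expect_error(mean_ci(1, 0, 10), "t = 0")
})

test_that("inter-operator CV is SD/mean in percent and scale-free", {
  expect_equal(inter_operator_cv(rep(3, 6)), 0)
  expect_equal(round(inter_operator_cv(c(10, 10, 10, 14)), 2), 18.18)
  x <- c(2, 3, 5, 7)
  expect_equal(inter_operator_cv(10 * x), inter_operator_cv(x),
               tolerance = 1e-12)
})

test_that("bootstrap CV change is seeded, reproducible and sane", {
  pre <- c(3.2, 4.1, 4.8, 3.9, 4.5, 3.6, 4.2, 4.9, 3.8, 4.0)
  post <- c(1.5, 1.9, 2.1, 1.7, 1.8, 1.6, 2.0, 1.9, 1.7, 1.8)
  b1 <- bootstrap_cv_change(pre, post, B = 2000, seed = 7)
  b2 <- bootstrap_cv_change(pre, post, B = 2000, seed = 7)
  expect_identical(b1$ci, b2$ci)
  expect_equal(b1$point,
               stats::sd(pre) / mean(pre) * 100 -
                 stats::sd(post) / mean(post) * 100)
  expect_true(b1$ci[1] <= b1$point && b1$point <= b1$ci[2])

  same <- bootstrap_cv_change(pre, pre, B = 500, seed = 1)
  expect_equal(same$point, 0)
  expect_true(same$ci[1] <= 0 && same$ci[2] >= 0)

  expect_warning(bootstrap_cv_change(pre, post, B = 50, seed = 1),
                 "B < 100")
  expect_error(bootstrap_cv_change(pre, post, B = 100), "seed")
})

test_that("bootstrap does not disturb the session RNG state", {
  set.seed(99)
  before <- stats::runif(1)
  set.seed(99)
  invisible(bootstrap_cv_change(c(3, 4, 5), c(1, 2, 2), B = 200, seed = 5))
  expect_identical(stats::runif(1), before)
})

test_that("exact McNemar matches the enumerated binomial oracle", {
  # all concordant: no discordant information
  m0 <- mcnemar_exact(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(m0$b + m0$c, 0)
  expect_equal(m0$p, 1)

  # b = 1, c = 9: oracle by explicit enumeration of the binomial tail
  pre <- c(rep(1, 1), rep(0, 9), rep(1, 3), rep(0, 3))
  post <- c(rep(0, 1), rep(1, 9), rep(1, 3), rep(0, 3))
  m <- mcnemar_exact(pre, post)
  expect_equal(m$b, 1)
  expect_equal(m$c, 9)
  oracle <- 2 * sum(choose(10, 0:1)) / 2^10
  expect_equal(m$p, oracle, tolerance = 1e-12)
  expect_equal(round(m$p, 6), 0.021484)

  # symmetric discordance: doubled tail caps at 1
  ms <- mcnemar_exact(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(ms$b, 2)
  expect_equal(ms$c, 2)
  expect_equal(ms$p, 1)

  expect_error(mcnemar_exact(c(1, 2), c(0, 1)), "0/1")
})

test_that("McNemar p depends only on the discordant counts", {
  base <- mcnemar_exact(c(1, 0, 0), c(0, 1, 1))
  padded <- mcnemar_exact(c(1, 0, 0, 1, 1, 0, 0), c(0, 1, 1, 1, 1, 0, 0))
  expect_identical(base$p, padded$p)
  expect_identical(base$b, padded$b)
})

test_that("improvement accounting is post minus pre in percentage points", {
  tbl <- improvement_table(c(45, 40, 30, 25), c(88, 80, 80, 70))
  expect_equal(tbl$improvement, c(43, 40, 50, 45))
  expect_equal(improvement_table(60, 60)$improvement, 0)
  expect_error(improvement_table(c(10, 20), 30), "equal length")
  expect_error(improvement_table(101, 50), "\\[0, 100\\]")
})
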