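test_that("rsd uses the sample SD over the mean, in percent", {
  expect_equal(rsd(c(100, 100, 100)), 0)
  expect_equal(rsd(c(98, 100, 102)), 2)          # sample SD = 2 exactly
  expect_equal(rsd(replicate_set(c(98, 100, 102))), 2)
})

test_that("rsd is invariant under positive rescaling", {
  set.seed(11)
  for (i in 1:20) {
    x <- stats::rlnorm(8, 3, 0.2)
    scale <- stats::runif(1, 0.01, 50)
    expect_equal(rsd(scale * x), rsd(x), tolerance = 1e-12)
  }
})

test_that("rsd rejects degenerate inputs", {
  expect_error(rsd(c(5)), "insufficient replicates")
  expect_error(rsd(c(-1, 1)), "zero mean")
})

test_that("type A evaluation returns SD/mean with optional sqrt(n) and dof", {
  u <- type_a_uncertainty(c(98, 100, 102))
  expect_equal(as.numeric(u), 0.02)
  expect_equal(attr(u, "dof"), 2L)
  u_mean <- type_a_uncertainty(c(98, 100, 102), of_mean = TRUE)
  expect_equal(as.numeric(u_mean), 2 / sqrt(3) / 100, tolerance = 1e-12)
  expect_equal(as.numeric(type_a_uncertainty(c(7, 7, 7, 7))), 0)
  expect_error(type_a_uncertainty(3), "insufficient")
})

test_that("type B divisors follow the assumed distribution", {
  expect_equal(type_b_uncertainty(1.0, "rectangular", nominal = 1.0),
               1 / sqrt(3), tolerance = 1e-12)
  expect_equal(type_b_uncertainty(0, "rectangular", nominal = 5), 0)
  expect_equal(type_b_uncertainty(0.6, "triangular", nominal = 100),
               0.6 / sqrt(6) / 100, tolerance = 1e-12)
  expect_equal(type_b_uncertainty(2, "normal", nominal = 10, k_source = 2),
               0.1, tolerance = 1e-12)
  expect_error(type_b_uncertainty(1, "uniformish", nominal = 1),
               "unknown distribution")
  expect_error(type_b_uncertainty(1, "normal", nominal = 1), "k_source")
  expect_error(type_b_uncertainty(1, "rectangular", nominal = 0),
               "non-zero")
})

test_that("root-sum-of-squares combination matches hand values", {
  expect_equal(combine_uncertainty(c(a = 3, b = 4)), 5)
  expect_equal(combine_uncertainty(c(only = 2.5)), 2.5)
  expect_equal(combine_uncertainty(five_source_u()), 0.125,
               tolerance = 1e-12)
  expect_error(combine_uncertainty(list()), "empty budget")
})

test_that("combination agrees with the explicit summation oracle and is monotone", {
  set.seed(42)
  for (i in 1:100) {
    rb <- random_budget()
    uc <- combine_uncertainty(rb$components)
    expect_equal(uc, combine_oracle(rb$u, rb$c), tolerance = 1e-12)
    # never less than any single contribution
    expect_true(uc >= max(abs(rb$c * rb$u)) - 1e-15)
    # appending a positive component strictly increases uc
    extra <- uncertainty_component("extra", u = stats::runif(1, 0.01, 0.1))
    expect_gt(combine_uncertainty(c(rb$components, list(extra))), uc)
    # order independence
    perm <- sample(seq_along(rb$components))
    expect_equal(combine_uncertainty(rb$components[perm]),
                 combine_oracle(rb$u[perm], rb$c[perm]),
                 tolerance = 1e-12)
  }
})

test_that("budget shares are squared contribution ratios summing to 100", {
  expect_equal(unname(budget_shares(c(a = 3, b = 4))), c(36, 64))
  expect_equal(unname(budget_shares(c(solo = 0.7))), 100)
  set.seed(7)
  for (i in 1:50) {
    rb <- random_budget()
    shares <- budget_shares(rb$components)
    expect_equal(sum(shares), 100, tolerance = 1e-9)
    expect_true(all(shares >= 0 & shares <= 100))
    perm <- sample(seq_along(rb$components))
    expect_equal(unname(budget_shares(rb$components[perm])),
                 unname(shares[perm]), tolerance = 1e-12)
  }
  expect_error(budget_shares(c(a = 0, b = 0)), "all-zero")
})

test_that("published five-source shares round-trip to 1 decimal", {
  shares <- budget_shares(five_source_u())
  expect_equal(round(shares[["Lab Card"]], 1), 47.7)
  expect_equal(round(shares[["Extractor"]], 1), 34.4)
  expect_equal(round(shares[["Sample Weighing"]], 1), 11.2)
  expect_equal(round(shares[["zero-card Calibration"]], 1), 6.1)
  expect_equal(round(shares[["Curve Fitting"]], 1), 0.6)
})

test_that("expansion is linear in uc and k", {
  expect_equal(expand_uncertainty(11.75, 2), 23.5)
  expect_equal(expand_uncertainty(0, 2), 0)
  expect_equal(expand_uncertainty(1, 3), 3)
  expect_equal(expand_uncertainty(2 * 1.3, 2), 2 * expand_uncertainty(1.3, 2))
  expect_error(expand_uncertainty(-1, 2), ">= 0")
  expect_error(expand_uncertainty(1, 0), "> 0")
})

test_that("measurement report reproduces the worked reporting format", {
  rep <- measurement_report(188.10, uc_rel = 11.75 / 188.10, k = 2)
  expect_equal(rep$U, 23.5, tolerance = 1e-12)
  expect_equal(rep$interval, c(164.6, 211.6), tolerance = 1e-10)
  expect_equal(rep$text, "188.10 ± 23.5 µg/kg (k = 2)")

  zero <- measurement_report(0, uc_rel = 0.1, k = 2)
  expect_equal(zero$interval, c(0, 0))
  expect_equal(zero$text, "0.00 ± 0.00 µg/kg (k = 2)")

  plain <- measurement_report(100, uc_rel = 0.05, k = 2)
  expect_equal(plain$U, 10)
  expect_equal(plain$interval, c(90, 110))
  expect_error(measurement_report(-1, 0.1), ">= 0")
})

test_that("report interval width equals 2U exactly", {
  set.seed(3)
  for (i in 1:25) {
    rep <- measurement_report(stats::runif(1, 0, 300),
                              uc_rel = stats::runif(1, 0, 0.3),
                              k = stats::runif(1, 1, 3))
    expect_equal(diff(rep$interval), 2 * rep$U, tolerance = 1e-12)
    expect_identical(rep$U, rep$k * rep$uc)
  }
})

test_that("relative expanded uncertainty is 100 U / X", {
  expect_equal(round(relative_expanded(188.10, 23.5), 1), 12.5)
  expect_equal(relative_expanded(100, 0), 0)
  expect_equal(relative_expanded(200, 50), 25)
  expect_error(relative_expanded(0, 1), "X > 0")
})
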