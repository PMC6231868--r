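# Testing track for a single proportion: MLE, null-based standard error,
# two-sided score test, and the test-inversion confidence interval.

test_that("the MLE is the success fraction and inputs are validated", {
  expect_equal(estimate_mle(binomial_count(540, 1000)), 0.54)
  expect_equal(estimate_mle(binomial_count(10, 1000)), 0.01)
  expect_equal(estimate_mle(binomial_count(0, 50)), 0)
  expect_error(binomial_count(5, 0), "trials")
  expect_error(binomial_count(-1, 10), "successes")
  expect_error(binomial_count(11, 10), "exceed")
  expect_error(binomial_count(2.5, 10), "whole")
})

test_that("the sampling standard error is computed under the null value", {
  expect_equal(round(sampling_se(0.5, 1000), 4), 0.0158)
  expect_equal(sampling_se(0.5, 4), 0.25)
  expect_equal(sampling_se(0.9, 100), 0.03)
  expect_error(sampling_se(0, 1000), "degenerate")
  expect_error(sampling_se(1, 1000), "degenerate")
})

test_that("the two-sided score test reproduces the coin-flip worked example", {
  d <- binomial_count(540, 1000)
  t1 <- null_test(d, 0.5)
  expect_equal(round(t1$p_one_sided, 4), 0.0057)
  expect_equal(round(t1$p_value, 4), 0.0114)
  expect_equal(round(null_test(d, 0.501)$p_value, 4), 0.0136)
  # null equal to the estimate: the doubled tail is capped at 1
  expect_equal(p_value_two_sided(d, 0.54), 1)
  expect_lte(p_value_two_sided(d, 0.5399), 1)
  expect_error(null_test(d, 0), "between 0 and 1")
})

test_that("P values decrease strictly as the null moves away from the MLE", {
  d <- binomial_count(540, 1000)
  below <- seq(0.46, 0.53, by = 0.005)
  above <- seq(0.55, 0.62, by = 0.005)
  p_below <- vapply(below, function(q) p_value_two_sided(d, q), numeric(1))
  p_above <- vapply(above, function(q) p_value_two_sided(d, q), numeric(1))
  expect_true(all(diff(p_below) > 0))   # approaching the MLE from below
  expect_true(all(diff(p_above) < 0))   # receding from the MLE above
})

test_that("test inversion matches the Wilson closed form and is self-consistent", {
  d <- binomial_count(540, 1000)
  ci <- invert_test_interval(d, level = 0.95, tolerance = 1e-8)
  expect_equal(round(ci$lower, 3), 0.509)
  expect_equal(round(ci$upper, 3), 0.571)

  set.seed(421)
  for (i in 1:100) {
    n <- sample(10:2000, 1)
    s <- sample(seq_len(n - 1), 1)
    dat <- binomial_count(s, n)
    ci <- invert_test_interval(dat, level = 0.95, tolerance = 1e-8)
    w <- wilson_ci(s, n)
    expect_equal(ci$lower, w[1], tolerance = 1e-6)
    expect_equal(ci$upper, w[2], tolerance = 1e-6)
    # endpoints reproduce P = 1 - level
    expect_lt(abs(p_value_two_sided(dat, ci$lower) - 0.05), 1e-6)
    expect_lt(abs(p_value_two_sided(dat, ci$upper) - 0.05), 1e-6)
    # the MLE sits inside its own interval
    qhat <- estimate_mle(dat)
    expect_true(ci$lower <= qhat && qhat <= ci$upper)
  }
})

test_that("intervals are symmetric at q-hat = 0.5 and nested across levels", {
  d <- binomial_count(500, 1000)
  ci <- invert_test_interval(d)
  expect_equal(ci$lower + ci$upper, 1, tolerance = 1e-7)

  d2 <- binomial_count(540, 1000)
  ci95 <- invert_test_interval(d2, level = 0.95)
  ci99 <- invert_test_interval(d2, level = 0.99)
  expect_lt(ci99$lower, ci95$lower)
  expect_gt(ci99$upper, ci95$upper)
})

test_that("the exact binomial test is available as an alternative method", {
  d <- binomial_count(540, 1000)
  expect_equal(p_value_two_sided(d, 0.5, method = "exact"),
               binom.test(540, 1000, 0.5)$p.value)
})
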