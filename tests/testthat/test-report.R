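# Report layer: the worked example end to end, CSV and JSON interfaces,
# rendering conventions, and byte-level determinism.

test_that("the coin-flip demo reproduces the worked example end to end", {
  rep <- run_coinflip_demo(540, 1000)
  r <- rep$rendered
  expect_equal(r$estimate, 0.54)
  expect_equal(r$se, 0.0158)
  expect_equal(r$p_value, 0.0114)
  expect_equal(r$ci_lower, 0.509)
  expect_equal(r$ci_upper, 0.571)
  expect_equal(r$tail_percent, 99)
  # rounded values trace back to stored unrounded ones
  expect_equal(r$p_value, round(rep$nhst$p_value, 4))
  expect_equal(r$tail_percent, round(100 * rep$bayes$tail_probability))
})

test_that("a fair-coin dataset gives P = 1 and a biased prior shifts the mode", {
  expect_equal(run_coinflip_demo(500, 1000)$nhst$p_value, 1)
  rep <- run_coinflip_demo(540, 1000, prior = prior_beta(900, 300))
  expect_gt(rep$bayes$posterior_mode, 0.6)
  expect_lt(rep$bayes$posterior_mode, 0.7)
})

test_that("priors parse from JSON config", {
  p <- prior_from_json('{"family":"beta","a":8,"b":3}')
  expect_equal(p$shape1, 8)
  expect_equal(p$shape2, 3)
  expect_equal(prior_from_json('{"family":"uniform"}')$family, "uniform")
  expect_error(prior_from_json('{"family":"gamma"}'), "unknown prior")
})

test_that("trial CSV round-trips and malformed rows are named", {
  d <- simulate_binary_trial(50, 0.3, 1.5, seed = 1)
  tf <- tempfile(fileext = ".csv")
  write_trial_csv(d, tf)
  back <- read_trial_csv(tf)
  expect_equal(back$outcome, d$outcome)
  expect_equal(attr(back, "outcome_type"), "binary")

  bad <- tempfile(fileext = ".csv")
  writeLines(c("arm,outcome", "control,1", "placebo,0"), bad)
  expect_error(read_trial_csv(bad), "row 2")
  unlink(c(tf, bad))
})

test_that("trial reports are deterministic and round-trip through JSON", {
  d <- simulate_binary_trial(300, 0.2, 1.5, seed = 12)
  cfg <- fast_config(seed = 40, iterations = 2500, burn_in = 500)
  # short runs: byte-level determinism, not convergence, is under test
  r1 <- suppressWarnings(run_trial_analysis(d, cfg))
  r2 <- suppressWarnings(run_trial_analysis(d, cfg))
  j1 <- write_report_json(r1)
  j2 <- write_report_json(r2)
  expect_identical(as.character(j1), as.character(j2))

  parsed <- jsonlite::fromJSON(as.character(j1))
  expect_identical(parsed$nhst$effect_estimate, r1$nhst$effect_estimate)
  expect_identical(parsed$bayes$probabilities, r1$bayes$probabilities)
  expect_identical(parsed$bayes$posterior_median, r1$bayes$posterior_median)
})

test_that("binary reports render exceedance tables and count reports bands", {
  d <- simulate_binary_trial(2000, 0.3, 1, seed = 21)
  cfg <- fast_config(seed = 41, iterations = 4000, burn_in = 1000)
  rep <- suppressWarnings(run_trial_analysis(d, cfg))
  expect_equal(rep$bayes$cutpoints, c(1, 1.5, 2, 2.5))
  expect_true(all(diff(rep$bayes$probabilities) <= 0))
  # at this scale Pr(OR > 1) tracks the normal-approximation probability
  # implied by the fitted log odds ratio (Bernstein-von Mises)
  fit <- fit_logistic_mle(d)
  expect_lt(abs(rep$bayes$probabilities[1] -
                  pnorm(fit$group_effect / fit$effect_se_log)), 0.05)

  dc <- simulate_count_trial(408, 12, 0.99, 1.5, seed = 22)
  repc <- suppressWarnings(run_trial_analysis(dc, cfg))
  expect_equal(repc$bayes$mode, "bands")
  expect_length(repc$bayes$probabilities, 4)
  expect_equal(sum(repc$bayes$probabilities), 1, tolerance = 1e-9)
  expect_match(repc$rendered$table_percent[1], "%$")
})
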