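# Flat-prior Metropolis posteriors for the trial models: reproducibility,
# symmetry, parameter recovery, diagnostics honesty, and threshold tables.

test_that("an identical seed reproduces every draw bit for bit", {
  d <- make_binary_dataset(60, 300, 75, 300)
  cfg <- fast_config(seed = 101, iterations = 1500, burn_in = 500)
  # short deliberately: determinism, not convergence, is under test
  s1 <- suppressWarnings(sample_logistic_posterior(d, cfg))
  s2 <- suppressWarnings(sample_logistic_posterior(d, cfg))
  expect_identical(s1$chains, s2$chains)
  expect_identical(s1$effect, s2$effect)
  # a different seed gives different draws
  s3 <- suppressWarnings(
    sample_logistic_posterior(d, fast_config(seed = 102,
                                             iterations = 1500,
                                             burn_in = 500)))
  expect_false(identical(s1$chains, s3$chains))
})

test_that("identical arms put about half the posterior mass above OR = 1", {
  d <- make_binary_dataset(120, 500, 120, 500)
  s <- sample_logistic_posterior(d, fast_config(seed = 7))
  p <- mean(s$effect > 1)
  expect_gte(p, 0.45)
  expect_lte(p, 0.55)
})

test_that("the posterior recovers a smoking-cessation-scale odds ratio", {
  d <- simulate_binary_trial(751, 0.11, 2.05, seed = 2024)
  s <- sample_logistic_posterior(d, fast_config(seed = 8))
  med <- median(s$effect)
  expect_gt(med, 2.05 * 0.75)
  expect_lt(med, 2.05 * 1.25)
  # Bernstein-von Mises: posterior mean of the coefficient sits within
  # two posterior SDs of the MLE
  fit <- fit_logistic_mle(d)
  draws <- unlist(lapply(s$chains, function(m) m[, "group_effect"]))
  expect_lt(abs(mean(draws) - fit$group_effect), 2 * sd(draws))
})

test_that("Pr(OR > 1) agrees with the independent-beta Monte Carlo oracle", {
  d <- simulate_binary_trial(500, 0.25, 1.3, seed = 99)
  cn <- bayesrct:::arm_counts(d)
  s <- sample_logistic_posterior(d, mcmc_config(chains = 4,
                                                iterations = 20000,
                                                burn_in = 5000, seed = 31))
  oracle <- beta_or_oracle(cn$s_c, cn$n_c, cn$s_i, cn$n_i, seed = 12)
  expect_lt(abs(mean(s$effect > 1) - oracle), 0.01)
})

test_that("deliberately short chains raise the R-hat flag", {
  d <- simulate_binary_trial(751, 0.11, 2.05, seed = 3)
  cfg <- mcmc_config(chains = 4, iterations = 100, burn_in = 50, seed = 5)
  expect_warning(s <- sample_logistic_posterior(d, cfg), "R-hat")
  expect_false(s$converged)
})

test_that("the sampler refuses separated data", {
  expect_error(sample_logistic_posterior(make_binary_dataset(0, 50, 20, 50),
                                         fast_config(seed = 1)),
               "improper")
})

test_that("identical count arms split posterior mass evenly around IRR = 1", {
  set.seed(55)
  y <- rnbinom(400, size = 1.5, mu = 12)
  d <- trial_dataset(rep(c("control", "intervention"), each = 400),
                     c(y, y), "count")
  s <- sample_negbin_posterior(d, fast_config(seed = 17))
  p <- mean(s$effect > 1)
  expect_gte(p, 0.45)
  expect_lte(p, 0.55)
})

test_that("an alcohol-trial-scale posterior concentrates near IRR = 1", {
  d <- simulate_count_trial(408, 12, 0.99, 1.5, seed = 77)
  s <- sample_negbin_posterior(d, fast_config(seed = 18))
  expect_gt(mean(s$effect > 0.9 & s$effect < 1.1), 0.8)
  # posterior mode region against the MLE fit
  fit <- fit_negbin_mle(d)
  expect_lt(abs(median(s$effect) - fit$effect_estimate), 0.05)
  expect_error(sample_negbin_posterior(
    trial_dataset(rep(c("control", "intervention"), each = 4),
                  c(0, 0, 0, 0, 1, 2, 1, 3), "count"),
    fast_config(seed = 1)), "zeros")
})

test_that("threshold tables count draws correctly and stay coherent", {
  expect_warning(
    tab <- effect_threshold_probabilities(c(0.5, 1.2, 1.7, 2.1),
                                          "exceedance", 1),
    "Monte Carlo")
  expect_equal(tab$probabilities, 0.75)

  set.seed(10)
  draws <- exp(rnorm(5000, 0.4, 0.5))
  exc <- effect_threshold_probabilities(draws, "exceedance",
                                        c(1, 1.5, 2, 2.5))
  expect_true(all(diff(exc$probabilities) <= 0))
  bands <- effect_threshold_probabilities(draws, "bands", c(0.9, 1, 1.1))
  expect_length(bands$probabilities, 4)
  expect_equal(sum(bands$probabilities), 1, tolerance = 1e-12)
  # bands are complementary to the exceedance tails at shared cutpoints
  expect_equal(bands$probabilities[1],
               1 - mean(draws >= 0.9), tolerance = 1e-12)
  expect_error(effect_threshold_probabilities(draws, "exceedance",
                                              c(2, 1)), "increasing")
})
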