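# Grid approximation of Bayes' theorem for a Bernoulli parameter, checked
# against the conjugate beta closed form and adaptive quadrature.

test_that("the likelihood curve peaks at the MLE and respects symmetry", {
  curve <- binomial_likelihood_curve(binomial_count(540, 1000))
  step <- curve$support[2] - curve$support[1]
  expect_lt(abs(curve$support[which.max(curve$values)] - 0.54), step + 1e-12)
  expect_equal(max(curve$values), 1)

  sym <- binomial_likelihood_curve(binomial_count(1, 2), grid_size = 1001)
  expect_equal(sym$values, rev(sym$values), tolerance = 1e-12)
  expect_error(binomial_count(0, 0), "trials")
  expect_error(binomial_likelihood_curve(binomial_count(1, 2), 50),
               "grid_size")
})

test_that("a flat-prior grid posterior matches the conjugate beta density", {
  post <- grid_posterior(prior_uniform(), binomial_count(540, 1000),
                         grid_size = 10001)
  expect_lt(max(abs(post$density - dbeta(post$support, 541, 461))), 1e-4)
  # uniform prior is exactly beta(1, 1)
  post_b11 <- grid_posterior(prior_beta(1, 1), binomial_count(540, 1000),
                             grid_size = 10001)
  expect_equal(post$density, post_b11$density, tolerance = 1e-12)
})

test_that("beta priors update by the conjugate rule on the grid", {
  set.seed(77)
  for (i in 1:10) {
    a <- runif(1, 1, 20)
    b <- runif(1, 1, 20)
    n <- sample(20:2000, 1)
    s <- rbinom(1, n, runif(1, 0.1, 0.9))
    post <- grid_posterior(prior_beta(a, b), binomial_count(s, n),
                           grid_size = 10001)
    expect_lt(max(abs(post$density -
                        dbeta(post$support, a + s, b + n - s))), 1e-3)
  }
  expect_equal(beta_conjugate_posterior(1, 1, binomial_count(540, 1000)),
               c(shape1 = 541, shape2 = 461))
  expect_equal(beta_conjugate_posterior(8, 3, binomial_count(2, 5)),
               c(shape1 = 10, shape2 = 6))
  expect_error(beta_conjugate_posterior(0, 1, binomial_count(1, 2)),
               "positive")
})

test_that("with no data the posterior is the prior", {
  post <- grid_posterior(prior_beta(8, 3), data = NULL, grid_size = 2001)
  expect_equal(post$density, dbeta(post$support, 8, 3), tolerance = 1e-6)
})

test_that("tail and band probabilities agree with quadrature oracles and add up", {
  post <- grid_posterior(prior_uniform(), binomial_count(540, 1000))
  # conjugate upper tail, and an adaptive-quadrature check of the same mass
  expect_lt(abs(tail_probability(post, 0.5) -
                  pbeta(0.5, 541, 461, lower.tail = FALSE)), 1e-5)
  quad <- integrate(function(x) dbeta(x, 541, 461), 0.5, 1,
                    rel.tol = 1e-10)$value
  expect_lt(abs(tail_probability(post, 0.5) - quad), 1e-5)
  expect_equal(round(100 * tail_probability(post, 0.5)), 99)

  expect_equal(tail_probability(post, -1), 1)
  expect_equal(tail_probability(post, 2), 0)
  expect_equal(band_probability(post, 0, 1), 1, tolerance = 1e-12)
  expect_lt(abs(band_probability(post, 0.5, 0.55) -
                  diff(pbeta(c(0.5, 0.55), 541, 461))), 1e-5)
  # exact additivity and tail/band complementarity
  expect_equal(band_probability(post, 0.4, 0.5) +
                 band_probability(post, 0.5, 0.6),
               band_probability(post, 0.4, 0.6), tolerance = 1e-12)
  expect_equal(tail_probability(post, 0.52) +
                 band_probability(post, 0, 0.52), 1, tolerance = 1e-10)
  expect_error(band_probability(post, 0.6, 0.5), "invalid band")
})

test_that("grid summaries match closed forms and concentrate correctly", {
  post <- grid_posterior(prior_uniform(), binomial_count(540, 1000))
  s <- summary(post)
  expect_equal(s$mean, 541 / 1002, tolerance = 1e-3)
  expect_lt(abs(s$mode - 0.54), 2e-4)
  expect_lt(s$ci_lower, s$mean)
  expect_gt(s$ci_upper, s$mean)

  sym <- grid_posterior(prior_beta(5, 5), data = NULL, grid_size = 2001)
  expect_equal(summary(sym)$mean, 0.5, tolerance = 1e-6)

  # interval width shrinks as the distribution concentrates
  widths <- vapply(c(10, 100, 1000), function(n) {
    p <- grid_posterior(prior_uniform(), binomial_count(round(0.6 * n), n))
    z <- summary(p)
    z$ci_upper - z$ci_lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("growing data overwhelm the prior", {
  # total-variation distance between the flat-prior and weak-prior
  # posteriors shrinks monotonically with the sample size (peak density
  # heights grow like sqrt(n), so the raw sup-norm would not)
  dist_at_n <- function(n) {
    s <- round(0.6 * n)
    flat <- grid_posterior(prior_uniform(), binomial_count(s, n))
    weak <- grid_posterior(prior_beta(20, 20), binomial_count(s, n))
    bayesrct:::trapz(flat$support, abs(flat$density - weak$density)) / 2
  }
  d <- vapply(c(10, 100, 1000, 10000), dist_at_n, numeric(1))
  expect_true(all(diff(d) < 0))
  expect_lt(d[4], 0.05)
})

test_that("a strongly biased prior drags the posterior mode upward", {
  # a very narrow prior centred near 0.75 must carry enough pseudo-flips
  # (here 1200) not to be overwhelmed by the 1000 real flips
  post <- grid_posterior(prior_beta(900, 300), binomial_count(540, 1000))
  mode <- post$support[which.max(post$density)]
  expect_gt(mode, 0.6)
  expect_lt(mode, 0.7)
})

test_that("degenerate priors are rejected", {
  expect_error(prior_tabulated(c(0.2, 0.3), c(0, 0)), "positive density")
  # support falling entirely between grid points leaves zero density
  narrow <- prior_tabulated(c(0.0003, 0.0007), c(1, 1))
  expect_error(grid_posterior(narrow, binomial_count(5, 10),
                              grid_size = 101), "degenerate")
})
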