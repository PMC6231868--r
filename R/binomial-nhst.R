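#' Summary counts of a Bernoulli experiment
#'
#' Bundles the observed side of a binomial experiment -- the number of
#' successes (heads, or "no" responses) out of a fixed number of trials.
#' This is the data object consumed by the testing track
#' ([estimate_mle()], [null_test()], [invert_test_interval()]) and by the
#' grid-based Bayesian track ([grid_posterior()]).
#'
#' @param successes Non-negative whole number of successes.
#' @param trials Positive whole number of trials; must be at least 1 and at
#'   least `successes`.
#' @return An object of class `binomial_count` with elements `successes`
#'   and `trials`.
#' @examples
#' binomial_count(540, 1000)
#' @export
binomial_count <- function(successes, trials) {
  if (!is_whole(trials) || length(trials) != 1L || trials < 1)
    stop("`trials` must be a single whole number >= 1", call. = FALSE)
  if (!is_whole(successes) || length(successes) != 1L || successes < 0)
    stop("`successes` must be a single whole number >= 0", call. = FALSE)
  if (successes > trials)
    stop("`successes` cannot exceed `trials`", call. = FALSE)
  structure(list(successes = as.numeric(round(successes)),
                 trials = as.numeric(round(trials))),
            class = "binomial_count")
}

#' @export
print.binomial_count <- function(x, ...) {
  cat(sprintf("Binomial count: %d successes / %d trials (fraction %.4g)\n",
              x$successes, x$trials, x$successes / x$trials))
  invisible(x)
}

as_binomial_count <- function(x) {
  if (inherits(x, "binomial_count")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(binomial_count(x[1], x[2]))
  stop("expected a `binomial_count` or a (successes, trials) pair",
       call. = FALSE)
}

#' Maximum likelihood estimate of a proportion
#'
#' For the Bernoulli model the MLE of the success probability is simply the
#' success fraction.
#'
#' @param data A [binomial_count()] (or `c(successes, trials)` pair).
#' @return The success fraction `successes / trials`.
#' @examples
#' estimate_mle(binomial_count(540, 1000)) # 0.54
#' @export
estimate_mle <- function(data) {
  data <- as_binomial_count(data)
  data$successes / data$trials
}

#' Standard error of the sampling distribution under a hypothesized value
#'
#' The normal approximation to the sampling distribution of the success
#' fraction has standard deviation `sqrt(q0 * (1 - q0) / trials)` when the
#' population value is `q0`.  Evaluating it at the null value (rather than
#' at the MLE) gives the score-test convention used throughout the package.
#'
#' @param q0 Hypothesized proportion, strictly between 0 and 1.
#' @param trials Positive whole number of trials.
#' @return The standard error, a positive number.
#' @examples
#' sampling_se(0.5, 1000) # ~0.0158
#' @export
sampling_se <- function(q0, trials) {
  if (!is.numeric(q0) || length(q0) != 1L || !is.finite(q0) ||
      q0 <= 0 || q0 >= 1)
    stop("degenerate null: `q0` must lie strictly between 0 and 1",
         call. = FALSE)
  if (!is_whole(trials) || trials < 1)
    stop("`trials` must be a whole number >= 1", call. = FALSE)
  sqrt(q0 * (1 - q0) / trials)
}

#' Score test of a point null for a single proportion
#'
#' Tests the null hypothesis that the population proportion equals
#' `null_value` using the normal approximation to the sampling distribution
#' with the standard error computed under the null (the score test).  The
#' two-sided P value doubles the tail beyond the observed estimate, capped
#' at 1.  An exact binomial test is available via `method = "exact"`.
#'
#' @param data A [binomial_count()].
#' @param null_value Hypothesized proportion, strictly inside (0, 1).
#' @param method `"normal"` (default, score test) or `"exact"`
#'   ([stats::binom.test()]).
#' @return An object of class `null_test_result` with elements
#'   `null_value`, `estimate`, `standard_error`, `z_statistic`,
#'   `p_one_sided`, `p_value` (two-sided), `sides`, and `method`.
#' @examples
#' null_test(binomial_count(540, 1000), 0.5) # P = .0114
#' @export
null_test <- function(data, null_value, method = c("normal", "exact")) {
  data <- as_binomial_count(data)
  method <- match.arg(method)
  check_scalar_prob(null_value, "null_value")
  qhat <- estimate_mle(data)
  se <- sampling_se(null_value, data$trials)
  z <- (qhat - null_value) / se
  p1 <- stats::pnorm(abs(z), lower.tail = FALSE)
  if (method == "normal") {
    p2 <- min(1, 2 * p1)
  } else {
    p2 <- stats::binom.test(data$successes, data$trials,
                            p = null_value)$p.value
  }
  structure(list(null_value = null_value, estimate = qhat,
                 standard_error = se, z_statistic = z,
                 p_one_sided = p1, p_value = p2,
                 sides = "two-sided", method = method),
            class = "null_test_result")
}

#' @export
print.null_test_result <- function(x, ...) {
  cat(sprintf("Score test of q = %g: estimate %.4f, SE %.4f, z %.3f, two-sided P %.4g (%s)\n",
              x$null_value, x$estimate, x$standard_error, x$z_statistic,
              x$p_value, x$method))
  invisible(x)
}

#' Two-sided P value against a point null
#'
#' Convenience wrapper around [null_test()] returning only the two-sided
#' P value.
#'
#' @inheritParams null_test
#' @return A number in [0, 1].
#' @export
p_value_two_sided <- function(data, null_value, method = "normal") {
  null_test(data, null_value, method = method)$p_value
}

#' Confidence interval by inverting the two-sided score test
#'
#' Constructs the confidence interval as the set of null values that the
#' two-sided score test cannot reject at level `1 - level`: the lowest and
#' highest values whose P value is at least `1 - level` become the limits.
#' The endpoints are located by deterministic root finding on each side of
#' the MLE; the result coincides with the Wilson score interval.
#'
#' @param data A [binomial_count()].
#' @param level Confidence level in (0, 1); default 0.95.
#' @param tolerance Location accuracy of each endpoint on the proportion
#'   scale; default 1e-8.
#' @return An object of class `interval_estimate` with elements `lower`,
#'   `upper`, `level`, and `method`.
#' @examples
#' invert_test_interval(binomial_count(540, 1000)) # (0.509, 0.571)
#' @export
invert_test_interval <- function(data, level = 0.95, tolerance = 1e-8) {
  data <- as_binomial_count(data)
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level) ||
      level <= 0 || level >= 1)
    stop("`level` must be a single number strictly between 0 and 1",
         call. = FALSE)
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance <= 0)
    stop("`tolerance` must be a positive number", call. = FALSE)
  alpha <- 1 - level
  qhat <- estimate_mle(data)
  eps <- 1e-9
  f <- function(q0) p_value_two_sided(data, q0) - alpha
  tol <- tolerance / 10

  lower <- if (qhat <= eps) 0 else if (f(eps) >= 0) 0 else
    stats::uniroot(f, lower = eps, upper = qhat, tol = tol)$root
  upper <- if (qhat >= 1 - eps) 1 else if (f(1 - eps) >= 0) 1 else
    stats::uniroot(f, lower = qhat, upper = 1 - eps, tol = tol)$root

  structure(list(lower = lower, upper = upper, level = level,
                 method = "test-inversion-score"),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf("%g%% CI (%s): [%.6g, %.6g]\n", 100 * x$level, x$method,
              x$lower, x$upper))
  invisible(x)
}
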