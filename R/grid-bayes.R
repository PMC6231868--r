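# Grid approximation of Bayes' theorem for a single Bernoulli parameter.
# Priors and posteriors are represented as densities tabulated on a fixed
# ordered grid over [0, 1]; all quadrature is composite trapezoid, and all
# likelihood arithmetic happens in log space with a max-shift before
# exponentiation so large experiments cannot overflow.

BETA_EDGE_EPS <- 1e-12  # beta densities are evaluated at clipped endpoints

#' Prior specifications for a Bernoulli parameter
#'
#' Three prior families for the success probability `q`: a uniform (flat)
#' prior on [0, 1], a beta prior with two positive shape parameters, and a
#' tabulated prior given as (value, density) pairs that is linearly
#' interpolated (zero outside its support).  A uniform prior is exactly a
#' beta(1, 1) prior.
#'
#' @param shape1,shape2 Positive shape parameters of the beta prior.
#' @param values,density Ordered support points in [0, 1] and their
#'   non-negative densities for the tabulated prior; at least one density
#'   must be positive.
#' @return An object of class `prior_spec`.
#' @examples
#' prior_uniform()
#' prior_beta(8, 3)
#' prior_tabulated(c(0.4, 0.5, 0.6), c(0, 1, 0))
#' @name priors
NULL

#' @rdname priors
#' @export
prior_uniform <- function() {
  structure(list(family = "uniform"), class = "prior_spec")
}

#' @rdname priors
#' @export
prior_beta <- function(shape1, shape2) {
  if (!is.numeric(shape1) || !is.numeric(shape2) || length(shape1) != 1L ||
      length(shape2) != 1L || shape1 <= 0 || shape2 <= 0 ||
      !is.finite(shape1) || !is.finite(shape2))
    stop("beta shapes must be single positive numbers", call. = FALSE)
  structure(list(family = "beta", shape1 = shape1, shape2 = shape2),
            class = "prior_spec")
}

#' @rdname priors
#' @export
prior_tabulated <- function(values, density) {
  if (length(values) != length(density) || length(values) < 2L)
    stop("`values` and `density` must have equal length >= 2", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1))
    stop("tabulated support must lie within [0, 1]", call. = FALSE)
  if (is.unsorted(values, strictly = TRUE))
    stop("`values` must be strictly increasing", call. = FALSE)
  if (any(!is.finite(density)) || any(density < 0))
    stop("densities must be finite and non-negative", call. = FALSE)
  if (all(density == 0))
    stop("tabulated prior must assign positive density somewhere",
         call. = FALSE)
  structure(list(family = "tabulated", values = as.numeric(values),
                 density = as.numeric(density)),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  msg <- switch(x$family,
    uniform = "uniform prior on [0, 1]",
    beta = sprintf("beta(%g, %g) prior", x$shape1, x$shape2),
    tabulated = sprintf("tabulated prior on %d support points",
                        length(x$values)))
  cat("Prior:", msg, "\n")
  invisible(x)
}

# Unnormalized prior density evaluated on a vector of points in [0, 1].
prior_density_at <- function(prior, x) {
  stopifnot(inherits(prior, "prior_spec"))
  switch(prior$family,
    uniform = rep(1, length(x)),
    beta = stats::dbeta(pmin(pmax(x, BETA_EDGE_EPS), 1 - BETA_EDGE_EPS),
                        prior$shape1, prior$shape2),
    tabulated = {
      d <- stats::approx(prior$values, prior$density, xout = x,
                         yleft = 0, yright = 0, ties = "ordered")$y
      d[is.na(d)] <- 0
      d
    })
}

#' Construct a grid distribution
#'
#' Normalizes a non-negative density tabulated on a strictly increasing
#' support so that its trapezoid integral is exactly 1.
#'
#' @param support Strictly increasing grid of values.
#' @param density Non-negative finite densities of the same length.
#' @return An object of class `grid_distribution` with fields `support`,
#'   `density`, and `grid_size`.
#' @export
grid_distribution <- function(support, density) {
  if (length(support) != length(density) || length(support) < 2L)
    stop("`support` and `density` must have equal length >= 2", call. = FALSE)
  if (is.unsorted(support, strictly = TRUE))
    stop("`support` must be strictly increasing", call. = FALSE)
  if (any(!is.finite(density)) || any(density < 0))
    stop("`density` must be finite and non-negative", call. = FALSE)
  z <- trapz(support, density)
  if (!is.finite(z) || z <= 0)
    stop("degenerate distribution: density integrates to zero", call. = FALSE)
  structure(list(support = as.numeric(support),
                 density = as.numeric(density) / z,
                 grid_size = length(support)),
            class = "grid_distribution")
}

#' @export
print.grid_distribution <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("Grid distribution on %d points in [%g, %g]; mean %.4f, mode %.4f\n",
              x$grid_size, min(x$support), max(x$support), s$mean, s$mode))
  invisible(x)
}

#' @export
as.data.frame.grid_distribution <- function(x, ...) {
  data.frame(value = x$support, density = x$density)
}

#' Binomial likelihood curve on a grid
#'
#' Evaluates, for every grid value of the success probability `q`, how
#' likely the observed data are: the curve is proportional to
#' `q^successes * (1-q)^failures`, computed in log space and exponentiated
#' against its maximum, so the curve peaks at 1 at the MLE grid point.
#' The curve is deliberately unnormalized -- it is a likelihood, not a
#' probability distribution.
#'
#' @param data A [binomial_count()].
#' @param grid_size Number of equally spaced grid points on [0, 1];
#'   at least 101.
#' @return An object of class `grid_curve` with fields `support` and
#'   `values` (maximum value 1).
#' @examples
#' binomial_likelihood_curve(binomial_count(540, 1000))
#' @export
binomial_likelihood_curve <- function(data, grid_size = 10001) {
  data <- as_binomial_count(data)
  if (!is_whole(grid_size) || grid_size < 101)
    stop("`grid_size` must be a whole number >= 101", call. = FALSE)
  x <- seq(0, 1, length.out = grid_size)
  ll <- binomial_loglik(data, x)
  structure(list(support = x, values = exp(ll - max(ll))),
            class = "grid_curve")
}

binomial_loglik <- function(data, x) {
  xc <- pmin(pmax(x, BETA_EDGE_EPS), 1 - BETA_EDGE_EPS)
  data$successes * log(xc) + (data$trials - data$successes) * log1p(-xc)
}

#' Grid posterior for a Bernoulli parameter
#'
#' Applies Bayes' theorem pointwise on the grid: the posterior density is
#' proportional to the product of the prior density and the binomial
#' likelihood, renormalized to integrate to 1 by trapezoid quadrature.
#' With `data = NULL` there is nothing to condition on and the prior is
#' returned (normalized on the grid).
#'
#' @param prior A [prior_uniform()], [prior_beta()], or [prior_tabulated()].
#' @param data A [binomial_count()], or `NULL` for the no-data case.
#' @param grid_size Number of grid points on [0, 1]; at least 101
#'   (default 10001).
#' @return A [grid_distribution()].
#' @examples
#' post <- grid_posterior(prior_uniform(), binomial_count(540, 1000))
#' tail_probability(post, 0.5) # ~0.99
#' @export
grid_posterior <- function(prior, data = NULL, grid_size = 10001) {
  stopifnot(inherits(prior, "prior_spec"))
  if (!is_whole(grid_size) || grid_size < 101)
    stop("`grid_size` must be a whole number >= 101", call. = FALSE)
  x <- seq(0, 1, length.out = grid_size)
  pd <- prior_density_at(prior, x)
  if (is.null(data)) {
    if (all(pd == 0))
      stop("degenerate posterior: prior density is zero on the whole grid",
           call. = FALSE)
    return(grid_distribution(x, pd))
  }
  data <- as_binomial_count(data)
  logpost <- log(pd) + binomial_loglik(data, x)  # log(0) = -Inf is fine
  m <- max(logpost)
  if (!is.finite(m))
    stop("degenerate posterior: the prior excludes the entire data-supported region",
         call. = FALSE)
  grid_distribution(x, exp(logpost - m))
}

#' Exact conjugate beta update
#'
#' For a beta(a, b) prior and binomial data the posterior is available in
#' closed form: beta(a + successes, b + failures).  Used as the exact
#' shortcut for the beta family and as the oracle the grid engine is
#' validated against.
#'
#' @param prior_a,prior_b Positive shape parameters of the beta prior.
#' @param data A [binomial_count()].
#' @return Named numeric vector `c(shape1, shape2)` of the posterior.
#' @examples
#' beta_conjugate_posterior(1, 1, binomial_count(540, 1000)) # (541, 461)
#' @export
beta_conjugate_posterior <- function(prior_a, prior_b, data) {
  if (!is.numeric(prior_a) || !is.numeric(prior_b) || prior_a <= 0 ||
      prior_b <= 0)
    stop("prior shapes must be positive", call. = FALSE)
  data <- as_binomial_count(data)
  c(shape1 = prior_a + data$successes,
    shape2 = prior_b + (data$trials - data$successes))
}

#' Posterior tail probability
#'
#' Trapezoid integral of the density above `threshold`, with linear
#' interpolation of the density at the threshold itself.  Thresholds at or
#' below the support return 1; at or above it, 0.
#'
#' @param dist A [grid_distribution()].
#' @param threshold A real number.
#' @return A probability in [0, 1].
#' @export
tail_probability <- function(dist, threshold) {
  stopifnot(inherits(dist, "grid_distribution"))
  x <- dist$support
  d <- dist$density
  if (threshold <= x[1]) return(1)
  if (threshold >= x[length(x)]) return(0)
  i <- findInterval(threshold, x)         # x[i] <= threshold < x[i + 1]
  dt <- d[i] + (d[i + 1] - d[i]) * (threshold - x[i]) / (x[i + 1] - x[i])
  partial <- (x[i + 1] - threshold) * (dt + d[i + 1]) / 2
  rest <- if (i + 1 < length(x)) trapz(x[(i + 1):length(x)], d[(i + 1):length(x)]) else 0
  min(1, max(0, partial + rest))
}

#' Posterior band probability
#'
#' Integral of the density over the interval `(low, high)`, computed as a
#' difference of tail probabilities so that adjacent bands add exactly.
#'
#' @param dist A [grid_distribution()].
#' @param low,high Band limits with `low < high`.
#' @return A probability in [0, 1].
#' @export
band_probability <- function(dist, low, high) {
  if (!is.numeric(low) || !is.numeric(high) || low >= high)
    stop("invalid band: `low` must be strictly less than `high`",
         call. = FALSE)
  tail_probability(dist, low) - tail_probability(dist, high)
}

#' Summarize a grid distribution
#'
#' Mean by trapezoid quadrature, mode as the argmax grid point, and a
#' central (equal-tail) credible interval at the requested level obtained
#' by inverting the cumulative distribution.
#'
#' @param object A [grid_distribution()].
#' @param level Credible level in (0, 1); default 0.95.
#' @param ... Unused.
#' @return A list with `mean`, `mode`, `ci_lower`, `ci_upper`, `level`.
#' @export
summary.grid_distribution <- function(object, level = 0.95, ...) {
  check_scalar_prob(level, "level")
  x <- object$support
  d <- object$density
  cdf <- cum_trapz(x, d)
  cdf <- cdf / cdf[length(cdf)]
  qf <- function(p) stats::approx(cdf, x, xout = p, ties = "ordered")$y
  a <- (1 - level) / 2
  list(mean = trapz(x, x * d),
       mode = x[which.max(d)],
       ci_lower = qf(a),
       ci_upper = qf(1 - a),
       level = level)
}
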