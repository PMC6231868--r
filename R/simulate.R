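# Seeded synthetic-data generators.  Defaults encode the study conditions
# the package is designed around: a smoking-cessation-style binary trial
# (1502 responders -> 751 per arm, control abstinence 11%, odds ratio
# 2.05) and an alcohol-reduction-style count trial (816 responders -> 408
# per arm, control mean 12 standard drinks/week, incidence-rate ratio
# 0.99, negative-binomial dispersion k = 1.5).  Each arm draws from its
# own random stream split off the master seed, so resizing one arm leaves
# the other arm's outcomes unchanged.

split_seeds <- function(seed, n) {
  set.seed(check_seed(seed))
  sample.int(2147483646L, n)
}

#' Simulate a coin-flip experiment
#'
#' Draws `n` independent Bernoulli flips with heads probability `prob`
#' from a seeded generator.
#'
#' @param n Number of flips; default 1000.
#' @param prob Heads probability in [0, 1]; default 0.5.
#' @param seed Integer seed; required.
#' @return A list of class `coin_sim` with `flips` (0/1 vector) and
#'   `count` (a [binomial_count()]).
#' @examples
#' simulate_coin(1000, 0.54, seed = 1)$count
#' @export
simulate_coin <- function(n = 1000, prob = 0.5, seed) {
  if (!is_whole(n) || n < 1) stop("`n` must be a whole number >= 1",
                                  call. = FALSE)
  check_scalar_prob(prob, "prob", open = FALSE)
  set.seed(check_seed(seed))
  flips <- stats::rbinom(n, 1L, prob)
  structure(list(flips = flips, count = binomial_count(sum(flips), n)),
            class = "coin_sim")
}

#' Intervention-arm proportion implied by a control proportion and odds ratio
#'
#' Applies the odds ratio to the control odds:
#' `odds_i = odds_ratio * p_c / (1 - p_c)`, then converts back to a
#' proportion.
#'
#' @param control_prop Control-arm proportion in (0, 1).
#' @param odds_ratio Positive odds ratio.
#' @return The implied intervention-arm proportion.
#' @examples
#' or_to_prop(0.2, 4) # 0.5
#' @export
or_to_prop <- function(control_prop, odds_ratio) {
  check_scalar_prob(control_prop, "control_prop")
  if (!is.numeric(odds_ratio) || odds_ratio <= 0 || !is.finite(odds_ratio))
    stop("`odds_ratio` must be a positive number", call. = FALSE)
  o <- odds_ratio * control_prop / (1 - control_prop)
  o / (1 + o)
}

#' Simulate a two-arm binary trial
#'
#' Control outcomes are Bernoulli with probability `control_prop`;
#' intervention outcomes are Bernoulli with the probability implied by
#' multiplying the control odds by `odds_ratio` (see [or_to_prop()]).
#'
#' @param n_per_arm Respondents per arm: a single number, or
#'   `c(control, intervention)`.  Default 751.
#' @param control_prop Control-arm success probability; default 0.11.
#' @param odds_ratio True odds ratio; default 2.05.
#' @param seed Integer seed; required.
#' @return A binary [trial_dataset()] with attribute `truth` recording
#'   the generating parameters.
#' @export
simulate_binary_trial <- function(n_per_arm = 751, control_prop = 0.11,
                                  odds_ratio = 2.05, seed) {
  n_per_arm <- rep_len(n_per_arm, 2L)
  if (any(!is_whole(n_per_arm)) || any(n_per_arm < 1))
    stop("`n_per_arm` must be whole numbers >= 1", call. = FALSE)
  p_i <- or_to_prop(control_prop, odds_ratio)
  if (p_i <= 0 || p_i >= 1)
    stop("implied intervention proportion lies outside (0, 1)",
         call. = FALSE)
  seeds <- split_seeds(seed, 2L)
  set.seed(seeds[1])
  y_c <- stats::rbinom(n_per_arm[1], 1L, control_prop)
  set.seed(seeds[2])
  y_i <- stats::rbinom(n_per_arm[2], 1L, p_i)
  out <- trial_dataset(rep(c("control", "intervention"), n_per_arm),
                       c(y_c, y_i), "binary")
  attr(out, "truth") <- list(control_prop = control_prop,
                             intervention_prop = p_i,
                             odds_ratio = odds_ratio, seed = seed)
  out
}

#' Simulate a two-arm count trial
#'
#' Outcomes are negative-binomial with arm means `control_mean` and
#' `control_mean * irr` and common dispersion `k`, in the
#' mean-dispersion parameterization with variance `m + m^2 / k` (large
#' `k` approaches Poisson).
#'
#' @param n_per_arm Respondents per arm (scalar or
#'   `c(control, intervention)`); default 408.
#' @param control_mean Control-arm mean count; default 12.
#' @param irr True incidence-rate ratio; default 0.99.
#' @param dispersion Positive dispersion `k`; default 1.5.
#' @param seed Integer seed; required.
#' @return A count [trial_dataset()] with attribute `truth`.
#' @export
simulate_count_trial <- function(n_per_arm = 408, control_mean = 12,
                                 irr = 0.99, dispersion = 1.5, seed) {
  n_per_arm <- rep_len(n_per_arm, 2L)
  if (any(!is_whole(n_per_arm)) || any(n_per_arm < 1))
    stop("`n_per_arm` must be whole numbers >= 1", call. = FALSE)
  if (!is.numeric(control_mean) || control_mean <= 0)
    stop("`control_mean` must be positive", call. = FALSE)
  if (!is.numeric(irr) || irr <= 0)
    stop("`irr` must be positive", call. = FALSE)
  if (!is.numeric(dispersion) || dispersion <= 0)
    stop("`dispersion` must be positive", call. = FALSE)
  seeds <- split_seeds(seed, 2L)
  set.seed(seeds[1])
  y_c <- stats::rnbinom(n_per_arm[1], size = dispersion, mu = control_mean)
  set.seed(seeds[2])
  y_i <- stats::rnbinom(n_per_arm[2], size = dispersion,
                        mu = control_mean * irr)
  out <- trial_dataset(rep(c("control", "intervention"), n_per_arm),
                       c(y_c, y_i), "count")
  attr(out, "truth") <- list(control_mean = control_mean, irr = irr,
                             dispersion = dispersion, seed = seed)
  out
}

#' Convert mean-dispersion to failures/success-probability form
#'
#' The negative binomial can equivalently be written in terms of a number
#' of failures `size` and a success probability `prob`; this helper maps
#' the (mean, dispersion) parameterization used throughout the package to
#' that form (`size = k`, `prob = k / (k + m)`).
#'
#' @param mean Positive mean.
#' @param dispersion Positive dispersion `k`.
#' @return Named vector `c(size, prob)`.
#' @export
nb_mean_to_prob <- function(mean, dispersion) {
  if (mean <= 0 || dispersion <= 0)
    stop("`mean` and `dispersion` must be positive", call. = FALSE)
  c(size = dispersion, prob = dispersion / (dispersion + mean))
}
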