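# Bayesian track for the trial models: adaptive random-walk Metropolis
# targeting likelihood x flat (improper uniform) priors on the coefficient
# scale.  Written in-package so that runs are exactly reproducible from a
# single integer seed.  The proposal is diagonal normal, pre-scaled by the
# Wald standard errors of the MLE fit; a single global step multiplier is
# tuned by Robbins-Monro stochastic approximation toward a 35% acceptance
# rate during burn-in and frozen afterwards.

#' MCMC configuration
#'
#' @param chains Number of chains (>= 2, so split R-hat is defined);
#'   default 4.
#' @param iterations Iterations per chain, including burn-in; default
#'   20000.
#' @param burn_in Iterations discarded (and used for step-size adaptation)
#'   per chain; must be smaller than `iterations`; default 10000.
#' @param seed Integer master seed; required.  The seed fully determines
#'   every draw of every chain.
#' @param step_scale Optional fixed step multiplier; `NULL` (default)
#'   enables adaptation during burn-in.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4L, iterations = 20000L,
                        burn_in = 10000L, seed, step_scale = NULL) {
  seed <- check_seed(seed)
  if (!is_whole(chains) || chains < 2)
    stop("`chains` must be a whole number >= 2", call. = FALSE)
  if (!is_whole(iterations) || iterations < 1)
    stop("`iterations` must be a positive whole number", call. = FALSE)
  if (!is_whole(burn_in) || burn_in < 0 || burn_in >= iterations)
    stop("`burn_in` must be a non-negative whole number < `iterations`",
         call. = FALSE)
  if (!is.null(step_scale) && (!is.numeric(step_scale) || step_scale <= 0))
    stop("`step_scale` must be NULL or a positive number", call. = FALSE)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 seed = seed, step_scale = step_scale),
            class = "mcmc_config")
}

# Core sampler.  log_target must return a finite value at `start`;
# non-finite proposals are rejected.
run_rw_metropolis <- function(log_target, start, start_se, config,
                              par_names) {
  n_par <- length(start)
  set.seed(config$seed)
  chain_seeds <- sample.int(2147483646L, config$chains)
  keep <- config$iterations - config$burn_in
  chains <- vector("list", config$chains)
  acc <- numeric(config$chains)
  for (k in seq_len(config$chains)) {
    set.seed(chain_seeds[k])
    theta <- start + stats::rnorm(n_par) * start_se
    lp <- log_target(theta)
    tries <- 0L
    while (!is.finite(lp) && tries < 100L) {
      theta <- start + stats::rnorm(n_par) * start_se
      lp <- log_target(theta)
      tries <- tries + 1L
    }
    if (!is.finite(lp))
      stop("could not initialise a chain at positive posterior density",
           call. = FALSE)
    adapt <- is.null(config$step_scale)
    log_lambda <- if (adapt) log(2.38 / sqrt(n_par)) else
      log(config$step_scale)
    draws <- matrix(NA_real_, keep, n_par,
                    dimnames = list(NULL, par_names))
    n_acc <- 0L
    for (i in seq_len(config$iterations)) {
      prop <- theta + exp(log_lambda) * start_se * stats::rnorm(n_par)
      lp_prop <- log_target(prop)
      a <- if (is.finite(lp_prop)) exp(min(0, lp_prop - lp)) else 0
      if (stats::runif(1) < a) {
        theta <- prop
        lp <- lp_prop
        if (i > config$burn_in) n_acc <- n_acc + 1L
      }
      if (adapt && i <= config$burn_in)
        log_lambda <- log_lambda + (a - 0.35) / i^0.6
      if (i > config$burn_in) draws[i - config$burn_in, ] <- theta
    }
    chains[[k]] <- draws
    acc[k] <- n_acc / keep
  }
  list(chains = chains, acceptance = acc)
}

# Split R-hat: each retained chain is halved, and the usual
# between/within variance ratio is computed over the 2 * chains halves.
split_rhat <- function(chains, j) {
  halves <- do.call(cbind, lapply(chains, function(m) {
    n <- nrow(m)
    h <- floor(n / 2)
    cbind(m[seq_len(h), j], m[(n - h + 1):n, j])
  }))
  n <- nrow(halves)
  mu <- colMeans(halves)
  s2 <- apply(halves, 2, stats::var)
  W <- mean(s2)
  B <- n * stats::var(mu)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Effective sample size from chain-averaged autocorrelations, truncated
# where consecutive lag-pair sums turn negative (Geyer-style).
ess_mean <- function(chains, j) {
  n <- nrow(chains[[1]])
  total <- n * length(chains)
  lag_max <- min(n - 1, 400)
  rho <- Reduce(`+`, lapply(chains, function(m) {
    v <- stats::var(m[, j])
    if (v == 0) return(rep(0, lag_max + 1))
    as.numeric(stats::acf(m[, j], lag.max = lag_max, plot = FALSE,
                          demean = TRUE)$acf)
  })) / length(chains)
  s <- 0
  t <- 2
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (!is.finite(pair) || pair <= 0) break
    s <- s + pair
    t <- t + 2
  }
  tau <- max(1, 1 + 2 * s)
  min(total, total / tau)
}

new_posterior_samples <- function(chains, par_names, effect_name, config,
                                  acceptance) {
  rhat <- vapply(seq_along(par_names), function(j) split_rhat(chains, j),
                 numeric(1))
  ess <- vapply(seq_along(par_names), function(j) ess_mean(chains, j),
                numeric(1))
  diagnostics <- data.frame(parameter = par_names, rhat = rhat, ess = ess)
  converged <- all(is.finite(rhat) & rhat <= 1.01)
  obj <- structure(list(
    chains = chains,
    parameters = par_names,
    effect = exp(unlist(lapply(chains, function(m) m[, "group_effect"]),
                        use.names = FALSE)),
    effect_name = effect_name,
    diagnostics = diagnostics,
    converged = converged,
    acceptance = acceptance,
    config = config), class = "posterior_samples")
  if (!converged)
    warning(sprintf(
      "split R-hat exceeds 1.01 for: %s; chains have not converged, treat posterior summaries with caution",
      paste(par_names[!(is.finite(rhat) & rhat <= 1.01)], collapse = ", ")),
      call. = FALSE)
  obj
}

#' @export
print.posterior_samples <- function(x, ...) {
  n <- length(x$effect)
  q <- stats::quantile(x$effect, c(0.5, 0.025, 0.975))
  cat(sprintf("Posterior samples: %d retained draws over %d chains (%s)\n",
              n, x$config$chains, x$effect_name))
  cat(sprintf("  median %s %.3f, central 95%% interval %.3f-%.3f\n",
              x$effect_name, q[1], q[2], q[3]))
  cat(sprintf("  converged: %s (max R-hat %.4f)\n",
              x$converged, max(x$diagnostics$rhat)))
  invisible(x)
}

#' Flat-prior posterior of a two-arm logistic model
#'
#' Samples the joint posterior of (intercept, group effect) of the
#' logistic regression of outcome on arm under improper uniform priors on
#' both coefficients, so the target is exactly the likelihood.  The
#' likelihood depends on the data only through the per-arm success counts,
#' making each evaluation O(1).  Derived odds-ratio draws are
#' `exp(group_effect)`.  Under complete separation the flat-prior
#' posterior is improper and the sampler refuses to run.
#'
#' @param data A binary [trial_dataset()].
#' @param config An [mcmc_config()].
#' @return A `posterior_samples` object with split R-hat and effective
#'   sample size per parameter; a warning is raised (and the `converged`
#'   flag cleared) when any R-hat exceeds 1.01.
#' @examples
#' d <- trial_from_counts(c(55, 500), c(90, 500))
#' s <- sample_logistic_posterior(d, mcmc_config(chains = 2,
#'   iterations = 2000, burn_in = 500, seed = 1))
#' mean(s$effect > 1)
#' @export
sample_logistic_posterior <- function(data, config) {
  stopifnot(inherits(data, "trial_dataset"), inherits(config, "mcmc_config"))
  if (outcome_type(data) != "binary")
    stop("expected a binary trial dataset", call. = FALSE)
  cn <- arm_counts(data)
  if (cn$s_c %in% c(0, cn$n_c) || cn$s_i %in% c(0, cn$n_i))
    stop(paste("complete separation: the flat-prior posterior is improper;",
               "refusing to sample"), call. = FALSE)
  mle <- fit_logistic_mle(data)
  log_target <- function(th) {
    if (any(abs(th) > 35)) return(-Inf)
    eta_c <- th[1]
    eta_i <- th[1] + th[2]
    cn$s_c * eta_c - cn$n_c * log1pexp(eta_c) +
      cn$s_i * eta_i - cn$n_i * log1pexp(eta_i)
  }
  out <- run_rw_metropolis(log_target,
                           start = c(mle$intercept, mle$group_effect),
                           start_se = mle$coef_se, config = config,
                           par_names = c("intercept", "group_effect"))
  new_posterior_samples(out$chains, c("intercept", "group_effect"),
                        "OR", config, out$acceptance)
}

#' Flat-prior posterior of a two-arm negative-binomial model
#'
#' Samples (intercept, group effect, log dispersion) of the
#' negative-binomial regression of the count outcome on arm.  Priors are
#' improper uniform on the two coefficients and flat on the dispersion
#' `k > 0`; since `k` is sampled on the log scale the Jacobian adds
#' `log(k)` to the log target.  Derived incidence-rate-ratio draws are
#' `exp(group_effect)`.  The likelihood is evaluated on the tabulated
#' outcome frequencies per arm, so its cost grows with the number of
#' distinct outcome values, not the number of subjects.
#'
#' @param data A count [trial_dataset()].
#' @param config An [mcmc_config()].
#' @return A `posterior_samples` object (see
#'   [sample_logistic_posterior()]).
#' @export
sample_negbin_posterior <- function(data, config) {
  stopifnot(inherits(data, "trial_dataset"), inherits(config, "mcmc_config"))
  if (outcome_type(data) != "count")
    stop("expected a count trial dataset", call. = FALSE)
  arms <- arm_outcomes(data)
  if (all(arms$control == 0) || all(arms$intervention == 0))
    stop("degenerate data: an arm is all zeros", call. = FALSE)
  tab_c <- table(arms$control)
  tab_i <- table(arms$intervention)
  v_c <- as.numeric(names(tab_c)); f_c <- as.numeric(tab_c)
  v_i <- as.numeric(names(tab_i)); f_i <- as.numeric(tab_i)
  start_fit <- tryCatch(fit_negbin_mle(data), error = function(e) NULL)
  if (!is.null(start_fit)) {
    start <- c(start_fit$intercept, start_fit$group_effect,
               log(start_fit$dispersion))
    start_se <- c(start_fit$coef_se,
                  max(start_fit$dispersion_se_log, 0.05, na.rm = TRUE))
  } else {
    m <- vapply(arms, mean, numeric(1))
    v <- vapply(arms, stats::var, numeric(1))
    k0 <- mean(pmin(pmax(m^2 / pmax(v - m, 1e-6), 0.05), 1e4))
    start <- c(log(m[["control"]]),
               log(m[["intervention"]] / m[["control"]]), log(k0))
    start_se <- c(0.1, 0.15, 0.3)
  }
  log_target <- function(th) {
    if (any(abs(th) > 35)) return(-Inf)
    mu_c <- exp(th[1])
    mu_i <- exp(th[1] + th[2])
    k <- exp(th[3])
    ll <- sum(f_c * stats::dnbinom(v_c, size = k, mu = mu_c, log = TRUE)) +
      sum(f_i * stats::dnbinom(v_i, size = k, mu = mu_i, log = TRUE))
    if (!is.finite(ll)) return(-Inf)
    ll + th[3]  # Jacobian: flat prior on k > 0, sampled as log k
  }
  pars <- c("intercept", "group_effect", "log_dispersion")
  out <- run_rw_metropolis(log_target, start = start, start_se = start_se,
                           config = config, par_names = pars)
  new_posterior_samples(out$chains, pars, "IRR", config, out$acceptance)
}
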