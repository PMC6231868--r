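# Independent oracles and small fixture builders used across tests.

# Wilson score interval via the standard test in stats, which computes the
# closed quadratic form (no continuity correction).
wilson_ci <- function(s, n, level = 0.95) {
  unname(stats::prop.test(s, n, conf.level = level,
                          correct = FALSE)$conf.int)
}

# Closed-form 2x2 odds ratio (intervention vs control).
or_2x2 <- function(s_c, n_c, s_i, n_i) {
  (s_i / (n_i - s_i)) / (s_c / (n_c - s_c))
}

# Monte-Carlo oracle for Pr(OR > 1): independent conjugate Beta posteriors
# on each arm's success probability, transformed to the odds-ratio scale.
beta_or_oracle <- function(s_c, n_c, s_i, n_i, ndraw = 1e6, seed = 1) {
  set.seed(seed)
  pc <- rbeta(ndraw, s_c + 1, n_c - s_c + 1)
  pi <- rbeta(ndraw, s_i + 1, n_i - s_i + 1)
  mean((pi / (1 - pi)) / (pc / (1 - pc)) > 1)
}

make_binary_dataset <- function(s_c, n_c, s_i, n_i) {
  trial_from_counts(c(s_c, n_c), c(s_i, n_i))
}

fast_config <- function(seed, chains = 2, iterations = 6000,
                        burn_in = 2000) {
  mcmc_config(chains = chains, iterations = iterations,
              burn_in = burn_in, seed = seed)
}
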