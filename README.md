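# bayesrct

Side-by-side null hypothesis significance testing (NHST) and Bayesian
analysis of binomial experiments and two-arm randomized controlled
trials, in R.

Trial reports usually stop at "significant or not." This package runs
both inferential tracks on the same data so their outputs can be
compared directly: the testing track answers *how surprising are these
data in a hypothesized world*, the Bayesian track answers *how probable
is each world given these data*. It is aimed at trialists and applied
biostatisticians who want posterior statements such as
Pr(OR > 1.5 | data) next to the familiar estimate / CI / P value row.

## What's inside

**Single proportion** (the coin-flip-style experiment, `s` successes in
`n` Bernoulli trials with unknown success probability `q`):

- MLE `q̂ = s/n`; score standard error `SE(q0) = sqrt(q0(1−q0)/n)`
  evaluated under the null;
- two-sided score test, `P = min(1, 2·Φ̄(|q̂−q0|/SE(q0)))`;
- confidence interval by test inversion — the set of nulls not rejected
  at the chosen level, located by deterministic root finding; it
  coincides with the Wilson score interval;
- grid approximation of Bayes' theorem (`posterior ∝ likelihood × prior`)
  on 10,001 points with uniform, beta, or tabulated priors, all
  arithmetic in log space; exact conjugate shortcut
  `Beta(a+s, b+n−s)`; posterior tail/band probabilities and summaries.

**Two-arm trials**:

- binary outcome: logistic regression MLE (odds ratio, Wald CI, P) and
  a flat-prior posterior of (intercept, log OR) sampled with adaptive
  random-walk Metropolis;
- count outcome: negative-binomial regression MLE (incidence-rate
  ratio, dispersion `k`, variance `m + m²/k`) and a flat-prior
  posterior of (intercept, log IRR, log k);
- split R-hat and effective-sample-size diagnostics (runs flagging
  R-hat > 1.01 warn and clear their `converged` flag);
- posterior threshold tables: exceedance columns `Pr(OR > 1.0, 1.5,
  2.0, 2.5)` or bands `Pr(IRR < 0.9), Pr(0.9 < IRR < 1.0), ...`.

**Synthetic data**: seeded generators for coin-flip sequences and
binary/count two-arm trials with known ground truth (per-arm random
streams split from one master seed), plus `run_recovery()` for
bias/RMSE/coverage studies.

**Reports**: `run_coinflip_demo()` and `run_trial_analysis()` produce
reports whose rendered values (paper-style rounding) sit next to their
full-precision counterparts, serialized to JSON byte-identically for
identical seeds. A thin CLI lives at `inst/cli/bayesrct.R` with
subcommands `coinflip`, `analyze`, `simulate`, `recover`.

## Worked example

A coin lands heads 540 times in 1000 flips. Is it fair?

```r
library(bayesrct)
run_coinflip_demo(540, 1000)
#> Testing track:
#>   MLE 0.540, SE 0.0158, two-sided P 0.0114 vs null 0.5
#>   95% CI by test inversion: 0.509-0.571
#> Bayesian track:
#>   Pr(q > 0.5 | data) = 99%  (posterior mean 0.5399, mode 0.5400)
```

Reading it: the MLE of the heads probability is 0.54; under the null
`q = 0.5` the sampling SE is 0.0158, and data this extreme arise with
two-sided probability .0114, so the null is rejected at .05 (but not at
.005). No null between 0.509 and 0.571 could be rejected. The Bayesian
track conditions the flat prior on the same data and reports a 99%
posterior probability that the coin favours heads — a statement about
`q` itself, not about hypothetical replications.

A two-arm trial goes through the same dual track:

```r
d   <- simulate_binary_trial(n_per_arm = 751, control_prop = 0.11,
                             odds_ratio = 2.05, seed = 42)
cfg <- mcmc_config(chains = 4, iterations = 20000, burn_in = 10000, seed = 7)
run_trial_analysis(d, cfg)
#> Testing track:
#>   OR 1.77, 95% CI 1.34-2.34, P <.001
#> Bayesian track:
#>   posterior median OR 1.782, 95% interval 1.350-2.374
#>         >1     >1.5       >2     >2.5
#>    100.00%   88.33%   20.95%    1.19%
```

The threshold row is the Bayesian deliverable: e.g. an 88% posterior
probability that the intervention multiplies the odds of success by
more than 1.5 — a quantity a decision maker can weigh directly.

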