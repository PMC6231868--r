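---
title: "Dual-track analysis of binomial experiments and two-arm trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-track analysis of binomial experiments and two-arm trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesrct)
```

## What the package computes

`bayesrct` answers the same scientific question two ways.  Given the data
of a binomial experiment -- $s$ successes out of $n$ Bernoulli trials with
unknown success probability $q$ -- or of a two-arm randomized trial, it
runs:

* a **testing track**: the maximum-likelihood estimate, a
  normal-approximation score test of a point null, and a confidence
  interval constructed by inverting that test; and
* a **Bayesian track**: the full posterior distribution of the quantity of
  interest ($q$ for a single proportion; an odds ratio or incidence-rate
  ratio for a trial), from which tail and band probabilities such as
  $\Pr(q > 0.5 \mid \text{data})$ or $\Pr(\mathrm{OR} > 1.5 \mid
  \text{data})$ are read off directly.

The two tracks are deliberately kept side by side: the first reports how
surprising the data would be in hypothesized worlds, the second reports
how probable each world is given the data.

## The testing track for one proportion

The model is $y_i \sim \text{Bernoulli}(q)$, whose MLE is $\hat q = s/n$.
The sampling distribution of $\hat q$ is approximated as normal.  Two
conventions exist for its standard deviation; `bayesrct` uses the **score
(null-based) standard error**

$$\mathrm{SE}(q_0) = \sqrt{q_0(1-q_0)/n},$$

evaluated at the hypothesized value $q_0$ rather than at $\hat q$.  For
$s = 540$, $n = 1000$, $q_0 = 0.5$ this gives $\mathrm{SE} = 0.015811$,
$z = 2.5298$, a one-sided tail of $0.0057$ and a two-sided P value of
$0.0114$; the MLE-based convention ($\mathrm{SE} = 0.015760$) would give
$0.0111$ instead.  The null-based convention is the one whose numbers the
report layer prints, and it is also what makes test inversion coincide
with the Wilson score interval.  The doubled tail is capped at 1, which
matters for nulls close to the MLE.

The confidence interval is built exactly as the narrative "raise the null
a little and redo the test" suggests: the lower limit is the smallest
$q_0$ whose two-sided P value still reaches $1 - \text{level}$, the upper
limit the largest.  Because the P value is continuous and monotone on
each side of $\hat q$, each limit is the root of
$p(q_0) - (1-\text{level})$ and is located with Brent's method
(`stats::uniroot`) on $(\varepsilon, \hat q]$ and $[\hat q, 1 -
\varepsilon)$, $\varepsilon = 10^{-9}$, to a tolerance of
`tolerance/10` (default `tolerance = 1e-8`).  This is a deterministic
refinement of a bisection scan: no grid is ever enumerated, and the
endpoint P values reproduce $1-\text{level}$ to well below $10^{-6}$.
The result agrees with the closed-form Wilson interval, which the test
suite checks over randomized cases against `prop.test(correct = FALSE)`.
Edge cases: $\hat q = 0$ (or 1) pins the corresponding limit to 0 (or 1),
and degenerate nulls $q_0 \in \{0, 1\}$ are rejected as errors rather
than producing a zero standard error.

```{r coin}
run_coinflip_demo(540, 1000)
```

## The Bayesian track on a grid

For a single proportion the posterior is computed directly from Bayes'
theorem, $\text{posterior} \propto \text{likelihood} \times
\text{prior}$, on a uniform grid of 10\,001 points spanning $[0, 1]$
(endpoints included).  Design choices that matter:

* **Log-space arithmetic.**  The binomial likelihood
  $q^s(1-q)^{n-s}$ underflows catastrophically for $n$ in the thousands;
  all products are therefore sums of logs, shifted by their maximum
  before exponentiation.  Grid endpoints are clipped to
  $[10^{-12}, 1-10^{-12}]$ before taking logs, which also keeps beta
  densities with unbounded endpoints finite.
* **Trapezoid quadrature throughout** -- normalization, means, tails,
  quantiles -- consistent with the piecewise-linear view of the tabulated
  density.  At grid size 10\,001 the quadrature error for posteriors
  arising from $n \le 10^5$ observations is below $10^{-4}$ in sup-norm
  against the conjugate closed form, and tail probabilities match
  `pbeta` and adaptive quadrature to $10^{-5}$.
* **Band probabilities as tail differences**, so adjacent bands add
  exactly and tails and bands are complementary to machine precision.
* **Whole-percent rounding only in the report layer**: the stored tail
  probability for the worked example is 0.994292; the report prints 99%.

Three prior families are supported: uniform (identically beta(1, 1)),
beta with arbitrary positive shapes, and tabulated (value, density)
pairs with linear interpolation.  The conjugate shortcut
`beta_conjugate_posterior()` returns the exact beta(a + s, b + n - s)
update and doubles as the independent oracle for the grid path.

Two facts about priors are worth internalizing.  First, once data
accumulate, reasonable priors stop mattering: the total-variation
distance between the flat-prior and beta(20, 20)-prior posteriors at a
fixed success fraction falls from 0.40 at $n = 10$ to 0.03 at
$n = 10^4$.  (Sup-norm is the wrong metric for this statement --
posterior densities grow like $\sqrt n$, so the sup-norm plateaus even
as the distributions merge; the package's tests therefore assert the
total-variation version.)  Second, a prior can only resist $n$
observations if it carries comparable information: the "strongly
biased coin" fixture used in tests and examples is beta(900, 300) --
mode 0.75, roughly 1200 pseudo-flips -- which is what it takes to hold
the posterior mode of 540/1000 data in the 0.6--0.7 range.  A
beta(150, 50) prior, though visually narrow, is overwhelmed to a mode
of 0.575.

## Trial models under flat priors

Two-arm trials are modelled with an intercept plus an arm indicator and
nothing else -- no covariate adjustment, responders only.

**Binary outcomes** use logistic regression; the effect measure is the
odds ratio $\mathrm{OR} = e^{\beta_1}$.  The MLE fit is IRLS
(`stats::glm`), and for this saturated two-group model it equals the
closed-form $2\times 2$ odds ratio.  Complete separation (an arm with
all-0 or all-1 outcomes) is detected up front and refused, because the
flat-prior posterior is improper there too.

**Count outcomes** use negative-binomial regression with log link in the
mean--dispersion parameterization, $\mathrm{Var}(y) = m + m^2/k$; the
effect measure is the incidence-rate ratio $\mathrm{IRR} = e^{\beta_1}$.
The MLE fit is `MASS::glm.nb` (or a fixed-dispersion GLM when $k$ is
supplied, which recovers Poisson regression as $k \to \infty$).  For the
two-group model the fitted IRR equals the ratio of arm means for any
$k$, which the tests exploit as a closed-form oracle.

The Bayesian fits place improper uniform priors on the coefficients --
"flat priors for all unknown quantities" read on the log-odds /
log-rate scale, so the target is exactly the likelihood -- and, for the
count model, a flat prior on the dispersion $k > 0$, sampled as
$\log k$ with the Jacobian term $\log k$ added to the log target.  Two
caveats are documented rather than hidden:

* Flat on the coefficient scale is *not* flat on the probability scale.
  The independent cross-check used in the tests draws arm proportions
  from independent Beta$(s+1, f+1)$ posteriors (flat on probabilities)
  and agrees with the sampler's $\Pr(\mathrm{OR} > 1)$ to within 0.01 at
  $n = 500$/arm -- close, not identical, and the gap shrinks with $n$.
* The flat dispersion prior is formally improper as $k \to \infty$,
  where the likelihood tends to the Poisson likelihood (a nonzero
  constant).  For genuinely overdispersed trial-scale data the
  likelihood deficit out there is hundreds of log units, so finite
  chains never wander into that region; a numeric guard additionally
  rejects proposals with any parameter beyond $\pm 35$.

### The sampler

Posteriors are drawn with random-walk Metropolis: a diagonal normal
proposal pre-scaled by the Wald standard errors of the MLE fit, with one
global step multiplier adapted by Robbins--Monro stochastic
approximation ($\log\lambda_{i+1} = \log\lambda_i + (a_i - 0.35) /
i^{0.6}$, targeting 35% acceptance) during burn-in and frozen
afterwards, which keeps the post-burn-in chain a valid time-homogeneous
Markov chain.  Defaults are 4 chains of 20\,000 iterations with 10\,000
burn-in.  Chains start at the MLE jittered by one standard error.  The
logistic likelihood is evaluated from the four per-arm sufficient
statistics (O(1) per evaluation); the negative-binomial likelihood from
the tabulated outcome frequencies per arm, so cost scales with distinct
outcome values rather than subjects.

Every run is fully determined by the single integer seed in
`mcmc_config()`: per-chain seeds are split from it, and identical
configurations reproduce every draw bit for bit.  Convergence is
monitored with split R-hat (each chain halved, between/within variance
ratio over the $2C$ halves) and a Geyer-truncated autocorrelation
estimate of effective sample size; any split R-hat above 1.01 clears the
`converged` flag and raises a warning -- deliberately short runs must
fail loudly, and the tests check that they do.

Threshold tables summarize the posterior the way trial reports read:
exceedance mode gives $\Pr(\text{effect} > c)$ for each cutpoint
(non-increasing by construction; rendered at two decimals), bands mode
partitions the axis at the cutpoints into left-closed cells whose
probabilities sum to one exactly (rendered at one decimal).

## The synthetic generator

No participant-level trial data ship with the package, so every pipeline
stage is exercised on synthetic trials with known ground truth.  The
generator's defaults are the package's reference study conditions,
chosen once:

* **Binary trial**: 751 respondents per arm (a 1502-responder trial
  split evenly), control proportion 0.11, odds ratio 2.05.  The arm size
  and effect size mirror a text-message smoking-cessation trial of that
  scale; the control abstinence proportion is not derivable from
  published summaries and 0.11 was fixed as a realistic cessation-rate
  choice.
* **Count trial**: 408 respondents per arm (an 816-responder trial),
  control mean 12 standard drinks per week, IRR 0.99, dispersion
  $k = 1.5$.  The dispersion is likewise not derivable from published
  summaries; $k = 1.5$ encodes the strong overdispersion typical of
  weekly alcohol-consumption counts (variance $\approx 8$ times the
  mean at $m = 12$).

Intervention-arm parameters are derived, never specified twice: the
binary generator applies the odds ratio to the control odds
(`or_to_prop()`), the count generator multiplies the control mean by the
IRR.  Each arm consumes its own random stream split from the master
seed, so resizing one arm leaves the other arm's draws untouched.
`run_recovery()` repeats simulate-then-fit with per-replication seeds
split from a master seed and aggregates log-scale bias, RMSE, and
interval coverage.

What the generator does *not* emulate -- and hence what passing tests do
not establish about real trials: covariate structure and adjustment,
nonresponse and dropout, zero-inflation beyond what the negative
binomial implies, clustering, and secondary outcomes.  Recovery results
speak to the correctness of the estimators under the stated models, not
to the robustness of those models.

## Problem sizes and numerical tolerances used in validation

The test suite validates, among other things: grid-vs-conjugate
agreement (sup-norm $< 10^{-3}$ over 50 randomized prior/data cases at
grid size 10\,001, $< 10^{-4}$ for the flat-prior worked example);
interval inversion against the Wilson closed form and endpoint P values
within $10^{-4}$ of 0.05 over 100 randomized cases; the logistic MLE
against the $2\times2$ closed form to $10^{-8}$ and the NB rate ratio
against the ratio of arm means to $10^{-6}$; sampler agreement with the
independent-beta Monte Carlo oracle to 0.01 at 500/arm (60\,000 retained
draws vs $10^6$ oracle draws); and 90% credible-interval coverage within
$0.90 \pm 0.05$ over 200 synthetic binary trials at true OR 1.5 with 300
subjects per arm and 2 chains $\times$ 3000 iterations per trial -- a
size at which the normal-approximation accuracy of the posterior is
comfortably sufficient and the whole study runs at desk scale.

## Known limitations

* The score test and its inverted interval are normal approximations;
  exact binomial tests are available (`method = "exact"`) but are not
  the default and have no inverted-interval counterpart here.
* Flat coefficient priors are a convention, not an endorsement: they are
  "flat" only on the chosen scale, and for small trials an informative
  prior would be both honest and beneficial.  Alternative priors are
  configurable for the single-proportion track but the GLM samplers are
  flat-prior by design.
* The random-walk sampler is adequate for 2--3 parameter posteriors; it
  is not meant for models with covariates, where gradient-based samplers
  would be the right tool.
* Improper posteriors are refused where detectable (separation) and
  documented where asymptotic (the dispersion tail).
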