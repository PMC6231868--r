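Package: bayesrct
Title: Side-by-Side Null Hypothesis Testing and Bayesian Reanalysis of
    Two-Arm Randomized Trials
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Runs the classical testing track and a Bayesian track side by
    side for binomial experiments and two-arm randomized controlled trials.
    The testing track provides maximum-likelihood estimation of a proportion,
    normal-approximation score tests against a point null, and confidence
    intervals constructed by inverting the test.  The Bayesian track provides
    grid approximation of Bayes' theorem for a single Bernoulli parameter
    with uniform, beta, or tabulated priors, exact conjugate beta updates,
    and flat-prior logistic and negative-binomial regression for trial
    effect measures (odds ratios and incidence-rate ratios) sampled with an
    adaptive random-walk Metropolis algorithm with split R-hat and effective
    sample size diagnostics.  Includes a seeded synthetic generator for
    coin-flip sequences and two-arm binary or count trials, parameter
    recovery studies, posterior threshold-probability tables, and a report
    layer with a thin command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
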