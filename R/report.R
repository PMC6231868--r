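# Report layer: runs both analysis tracks end to end and renders
# paper-style output.  Every rendered (rounded) value is stored alongside
# its unrounded counterpart, and provenance carries the input checksum,
# configuration, seed and package version -- but no timestamp, so the same
# seed and input give byte-identical JSON.

pkg_version <- function() as.character(utils::packageVersion("bayesrct"))

dataset_checksum <- function(data) {
  tf <- tempfile(fileext = ".csv")
  on.exit(unlink(tf))
  write_trial_csv(data, tf)
  unname(tools::md5sum(tf))
}

prior_as_list <- function(prior) {
  unclass(prior)
}

#' Build a prior from a JSON specification
#'
#' Accepts a JSON string or file such as `{"family":"beta","a":8,"b":3}`,
#' `{"family":"uniform"}`, or
#' `{"family":"tabulated","values":[...],"density":[...]}`.
#'
#' @param json A JSON string or path to a JSON file.
#' @return A `prior_spec`.
#' @export
prior_from_json <- function(json) {
  x <- if (file.exists(json)) jsonlite::read_json(json, simplifyVector = TRUE)
       else jsonlite::fromJSON(json)
  family <- x$family
  if (is.null(family)) stop("prior JSON needs a `family` field",
                            call. = FALSE)
  switch(family,
    uniform = prior_uniform(),
    beta = prior_beta(x$a %||% x$shape1, x$b %||% x$shape2),
    tabulated = prior_tabulated(x$values, x$density),
    stop(sprintf("unknown prior family '%s'", family), call. = FALSE))
}

#' Full dual-track analysis of a binomial experiment
#'
#' Runs the complete worked analysis of a successes/trials experiment:
#' the testing track (MLE, null-based standard error, two-sided score
#' P value against `null_value`, test-inversion confidence interval) and
#' the Bayesian track (grid posterior under the requested prior, posterior
#' probability that the proportion exceeds `null_value`, posterior
#' summaries).  The `rendered` section rounds the way results are
#' conventionally printed: estimate and limits to 3 decimals, SE and
#' P value to 4, tail probability to a whole percent.
#'
#' @param successes,trials The observed counts.
#' @param prior A `prior_spec`; default flat.
#' @param level Confidence/credible level; default 0.95.
#' @param null_value Point null and posterior threshold; default 0.5.
#' @param grid_size Grid resolution for the posterior; default 10001.
#' @return An `analysis_report` list with `nhst`, `bayes`, `rendered`,
#'   and `provenance` sections (the grid posterior itself is attached as
#'   attribute `posterior`).
#' @examples
#' run_coinflip_demo(540, 1000)
#' @export
run_coinflip_demo <- function(successes, trials, prior = prior_uniform(),
                              level = 0.95, null_value = 0.5,
                              grid_size = 10001) {
  data <- binomial_count(successes, trials)
  test <- null_test(data, null_value)
  ci <- invert_test_interval(data, level = level)
  posterior <- grid_posterior(prior, data, grid_size = grid_size)
  tail <- tail_probability(posterior, null_value)
  ps <- summary(posterior, level = level)
  report <- structure(list(
    nhst = list(estimate = test$estimate, se = test$standard_error,
                z = test$z_statistic, p_one_sided = test$p_one_sided,
                p_value = test$p_value, null_value = null_value,
                ci_lower = ci$lower, ci_upper = ci$upper, level = level,
                method = ci$method),
    bayes = list(tail_threshold = null_value, tail_probability = tail,
                 posterior_mean = ps$mean, posterior_mode = ps$mode,
                 ci_lower = ps$ci_lower, ci_upper = ps$ci_upper,
                 level = level, grid_size = grid_size,
                 prior = prior_as_list(prior)),
    rendered = list(estimate = round(test$estimate, 3),
                    se = round(test$standard_error, 4),
                    p_value = round(test$p_value, 4),
                    ci_lower = round(ci$lower, 3),
                    ci_upper = round(ci$upper, 3),
                    tail_percent = round(100 * tail)),
    provenance = list(successes = data$successes, trials = data$trials,
                      version = pkg_version())),
    class = "analysis_report")
  attr(report, "posterior") <- posterior
  report
}

#' Full dual-track analysis of a two-arm trial
#'
#' Dispatches on the outcome type: binary trials get a logistic MLE fit
#' and a flat-prior logistic posterior with an exceedance threshold table
#' (default cutpoints 1.0, 1.5, 2.0, 2.5 on the odds ratio); count trials
#' get a negative-binomial MLE fit and posterior with a bands table
#' (default cutpoints 0.9, 1.0, 1.1 on the incidence-rate ratio).
#'
#' @param dataset A [trial_dataset()].
#' @param config An [mcmc_config()].
#' @param cutpoints Optional cutpoints overriding the defaults.
#' @param level Interval level; default 0.95.
#' @return An `analysis_report` with `nhst` (the MLE fit summary),
#'   `bayes` (posterior summaries, diagnostics and the threshold table),
#'   `rendered` (percentages at the conventional precision: two decimals
#'   for exceedance, one for bands), and `provenance` (input checksum,
#'   configuration, seed, version).  The `posterior_samples` object is
#'   attached as attribute `samples`.
#' @export
run_trial_analysis <- function(dataset, config, cutpoints = NULL,
                               level = 0.95) {
  stopifnot(inherits(dataset, "trial_dataset"),
            inherits(config, "mcmc_config"))
  binary <- outcome_type(dataset) == "binary"
  if (is.null(cutpoints))
    cutpoints <- if (binary) c(1, 1.5, 2, 2.5) else c(0.9, 1, 1.1)
  mode <- if (binary) "exceedance" else "bands"
  fit <- if (binary) fit_logistic_mle(dataset, level = level)
         else fit_negbin_mle(dataset, level = level)
  samples <- if (binary) sample_logistic_posterior(dataset, config)
             else sample_negbin_posterior(dataset, config)
  tab <- effect_threshold_probabilities(samples, mode, cutpoints)
  a <- (1 - level) / 2
  q <- stats::quantile(samples$effect, c(a, 0.5, 1 - a), names = FALSE)
  report <- structure(list(
    nhst = list(effect_name = fit$effect_name,
                effect_estimate = fit$effect_estimate,
                group_effect = fit$group_effect,
                effect_se_log = fit$effect_se_log,
                ci_lower = fit$wald_ci$lower,
                ci_upper = fit$wald_ci$upper,
                level = level, p_value = fit$p_value,
                dispersion = fit$dispersion),
    bayes = list(effect_name = samples$effect_name,
                 posterior_median = q[2],
                 ci_lower = q[1], ci_upper = q[3], level = level,
                 mode = mode, cutpoints = cutpoints,
                 labels = tab$labels,
                 probabilities = tab$probabilities,
                 retained_draws = length(samples$effect),
                 diagnostics = samples$diagnostics,
                 converged = samples$converged),
    rendered = list(effect = round(fit$effect_estimate, 2),
                    ci = sprintf("%.2f-%.2f", fit$wald_ci$lower,
                                 fit$wald_ci$upper),
                    p_value = if (fit$p_value < 0.001) "<.001"
                              else sprintf("%.3f", fit$p_value),
                    table_percent = sprintf(
                      if (binary) "%.2f%%" else "%.1f%%",
                      100 * tab$probabilities)),
    provenance = list(checksum = dataset_checksum(dataset),
                      outcome_type = outcome_type(dataset),
                      n = nrow(dataset),
                      config = unclass(config)[c("chains", "iterations",
                                                 "burn_in", "seed")],
                      version = pkg_version())),
    class = "analysis_report")
  attr(report, "samples") <- samples
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  if (!is.null(x$nhst$estimate)) {
    cat("Testing track:\n")
    cat(sprintf("  MLE %.3f, SE %.4f, two-sided P %.4f vs null %g\n",
                x$nhst$estimate, x$nhst$se, x$nhst$p_value,
                x$nhst$null_value))
    cat(sprintf("  %g%% CI by test inversion: %.3f-%.3f\n",
                100 * x$nhst$level, x$nhst$ci_lower, x$nhst$ci_upper))
    cat("Bayesian track:\n")
    cat(sprintf("  Pr(q > %g | data) = %d%%  (posterior mean %.4f, mode %.4f)\n",
                x$bayes$tail_threshold, x$rendered$tail_percent,
                x$bayes$posterior_mean, x$bayes$posterior_mode))
  } else {
    cat("Testing track:\n")
    cat(sprintf("  %s %s, %g%% CI %s, P %s\n", x$nhst$effect_name,
                format(x$rendered$effect), 100 * x$nhst$level,
                x$rendered$ci, x$rendered$p_value))
    cat("Bayesian track:\n")
    cat(sprintf("  posterior median %s %.3f, %g%% interval %.3f-%.3f\n",
                x$bayes$effect_name, x$bayes$posterior_median,
                100 * x$bayes$level, x$bayes$ci_lower, x$bayes$ci_upper))
    out <- format(rbind(x$bayes$labels, x$rendered$table_percent),
                  justify = "right")
    cat(paste("  ", apply(out, 1, paste, collapse = "  "),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' Writes the report at full double precision so that re-parsing the JSON
#' reproduces every unrounded value exactly; the heavy posterior objects
#' attached as attributes are not serialized.
#'
#' @param report An `analysis_report`.
#' @param path Optional output path; `NULL` returns the JSON string.
#' @return The JSON string (invisibly when written to `path`).
#' @export
write_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "analysis_report"))
  json <- jsonlite::toJSON(unclass(report), digits = I(17), auto_unbox = TRUE,
                           dataframe = "columns", null = "null",
                           pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Kernel density export of posterior effect draws
#'
#' Gaussian kernel density of the effect-measure draws with Silverman's
#' rule-of-thumb bandwidth, returned as a (value, density) data frame
#' ready to be written as CSV for downstream plotting.
#'
#' @param samples A `posterior_samples` object.
#' @param n Number of evaluation points; default 512.
#' @return A data frame with columns `value` and `density`.
#' @export
posterior_density <- function(samples, n = 512) {
  stopifnot(inherits(samples, "posterior_samples"))
  d <- stats::density(samples$effect, bw = "nrd0", n = n)
  data.frame(value = d$x, density = d$y)
}
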