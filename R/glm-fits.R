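# Frequentist track for the two trial models: logistic regression on the
# binary outcome (odds ratio) and negative-binomial regression on the
# count outcome (incidence-rate ratio).  Both models contain only an
# intercept and the arm indicator.  Fitting is delegated to the standard
# IRLS machinery in stats::glm / MASS::glm.nb; this module adds the
# trial-specific validation, effect-scale summaries and error handling.

new_glm_fit <- function(intercept, group_effect, effect_se_log, p_value,
                        effect_name, n, coef_se, dispersion = NULL,
                        dispersion_se_log = NULL, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(
    intercept = intercept,
    group_effect = group_effect,
    effect_estimate = exp(group_effect),
    effect_se_log = effect_se_log,
    wald_ci = structure(list(lower = exp(group_effect - z * effect_se_log),
                             upper = exp(group_effect + z * effect_se_log),
                             level = level, method = "wald-log-scale"),
                        class = "interval_estimate"),
    p_value = p_value,
    effect_name = effect_name,
    dispersion = dispersion,
    dispersion_se_log = dispersion_se_log,
    coef_se = coef_se,
    n = n), class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("%s %.3f, %g%% CI %.3f-%.3f, P %s  (n = %d)\n",
              x$effect_name, x$effect_estimate, 100 * x$wald_ci$level,
              x$wald_ci$lower, x$wald_ci$upper,
              if (x$p_value < 0.001) "<.001" else sprintf("%.3f", x$p_value),
              x$n))
  if (!is.null(x$dispersion))
    cat(sprintf("  dispersion k = %.3f\n", x$dispersion))
  invisible(x)
}

#' Logistic regression fit of a two-arm binary trial
#'
#' Maximum-likelihood logistic regression of the outcome on the arm
#' indicator, reported on the odds-ratio scale: the group coefficient is
#' the log odds ratio of the intervention arm versus control.  For this
#' saturated two-group model the estimate equals the closed-form 2x2-table
#' odds ratio.  Wald standard errors come from the observed information;
#' the two-sided P value tests a zero group effect.
#'
#' @param data A binary [trial_dataset()].
#' @param level Confidence level for the Wald interval (default 0.95).
#' @return A `glm_fit` with `effect_name = "OR"`.
#' @examples
#' d <- trial_from_counts(c(55, 500), c(90, 500))
#' fit_logistic_mle(d)
#' @export
fit_logistic_mle <- function(data, level = 0.95) {
  stopifnot(inherits(data, "trial_dataset"))
  if (outcome_type(data) != "binary")
    stop("logistic regression needs a binary trial dataset", call. = FALSE)
  cn <- arm_counts(data)
  if (cn$s_c %in% c(0, cn$n_c) || cn$s_i %in% c(0, cn$n_i))
    stop(paste("complete separation: an arm has all-0 or all-1 outcomes;",
               "the odds ratio is not identifiable"), call. = FALSE)
  arm <- factor(c("control", "intervention"),
                levels = c("control", "intervention"))
  resp <- cbind(c(cn$s_c, cn$s_i), c(cn$n_c - cn$s_c, cn$n_i - cn$s_i))
  fit <- stats::glm(resp ~ arm, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 100))
  co <- summary(fit)$coefficients
  b1 <- co["armintervention", "Estimate"]
  se1 <- co["armintervention", "Std. Error"]
  new_glm_fit(intercept = co["(Intercept)", "Estimate"],
              group_effect = b1, effect_se_log = se1,
              p_value = 2 * stats::pnorm(-abs(b1 / se1)),
              effect_name = "OR", n = cn$n_c + cn$n_i,
              coef_se = c(co["(Intercept)", "Std. Error"], se1),
              level = level)
}

#' Negative-binomial regression fit of a two-arm count trial
#'
#' Maximum-likelihood negative-binomial regression (log link,
#' mean-dispersion parameterization with variance `m + m^2/k`) of the
#' count outcome on the arm indicator, reported on the incidence-rate
#' ratio scale.  The dispersion `k` is estimated jointly unless fixed via
#' `dispersion`, in which case the model reduces to a GLM with a known
#' shape (large `k` approaches Poisson regression).  For the two-group
#' model the fitted IRR equals the ratio of arm sample means.
#'
#' @param data A count [trial_dataset()].
#' @param dispersion Optional fixed positive dispersion `k`; `NULL`
#'   (default) estimates it.
#' @param level Confidence level for the Wald interval (default 0.95).
#' @return A `glm_fit` with `effect_name = "IRR"` and the `dispersion`
#'   field populated.
#' @export
fit_negbin_mle <- function(data, dispersion = NULL, level = 0.95) {
  stopifnot(inherits(data, "trial_dataset"))
  if (outcome_type(data) != "count")
    stop("negative-binomial regression needs a count trial dataset",
         call. = FALSE)
  if (all(data$outcome == 0))
    stop("degenerate data: all outcomes are zero", call. = FALSE)
  if (stats::var(data$outcome) == 0)
    stop("degenerate data: outcomes have zero variance", call. = FALSE)
  df <- data.frame(arm = data$arm, outcome = data$outcome)
  if (is.null(dispersion)) {
    fit <- tryCatch(
      MASS::glm.nb(outcome ~ arm, data = df,
                   control = stats::glm.control(epsilon = 1e-10,
                                                maxit = 100)),
      error = function(e)
        stop(sprintf("negative-binomial fit failed: %s",
                     conditionMessage(e)), call. = FALSE))
    if (!fit$converged)
      stop("negative-binomial fit did not converge", call. = FALSE)
    k <- fit$theta
    k_se_log <- fit$SE.theta / fit$theta
  } else {
    if (!is.numeric(dispersion) || dispersion <= 0)
      stop("`dispersion` must be a positive number", call. = FALSE)
    fit <- stats::glm(outcome ~ arm, data = df,
                      family = MASS::negative.binomial(theta = dispersion),
                      control = stats::glm.control(epsilon = 1e-10,
                                                   maxit = 100))
    k <- dispersion
    k_se_log <- NULL
  }
  # dispersion = 1: Wald SEs from the NB information itself, not a
  # Pearson-rescaled quasi fit
  co <- summary(fit, dispersion = 1)$coefficients
  b1 <- co["armintervention", "Estimate"]
  se1 <- co["armintervention", "Std. Error"]
  new_glm_fit(intercept = co["(Intercept)", "Estimate"],
              group_effect = b1, effect_se_log = se1,
              p_value = 2 * stats::pnorm(-abs(b1 / se1)),
              effect_name = "IRR", n = nrow(df),
              coef_se = c(co["(Intercept)", "Std. Error"], se1),
              dispersion = k, dispersion_se_log = k_se_log,
              level = level)
}
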