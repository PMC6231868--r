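#' Posterior threshold-probability table
#'
#' Turns posterior effect-measure draws (odds ratios or incidence-rate
#' ratios) into the table of posterior probabilities used to report a
#' Bayesian trial analysis.  In `"exceedance"` mode each entry is the
#' fraction of draws strictly greater than a cutpoint (e.g. Pr(OR > 1.0),
#' Pr(OR > 1.5), ...), which is non-increasing in the cutpoint.  In
#' `"bands"` mode consecutive cutpoints partition the positive axis into
#' cells (below the first cutpoint, between consecutive ones, above the
#' last); cells are left-closed so the probabilities sum to 1 exactly.
#'
#' Fewer than 1000 draws triggers a warning: the table is still computed
#' but its entries carry visible Monte Carlo error.
#'
#' @param samples A `posterior_samples` object or a numeric vector of
#'   positive effect draws.
#' @param mode `"exceedance"` or `"bands"`.
#' @param cutpoints Strictly increasing positive cutpoints.
#' @return An object of class `threshold_table` with fields `mode`,
#'   `cutpoints`, `probabilities`, `labels`, `effect_name`, `n_draws`.
#' @examples
#' effect_threshold_probabilities(runif(2000, 0.5, 3), "exceedance",
#'                                c(1, 1.5, 2, 2.5))
#' @export
effect_threshold_probabilities <- function(samples,
                                           mode = c("exceedance", "bands"),
                                           cutpoints) {
  mode <- match.arg(mode)
  if (inherits(samples, "posterior_samples")) {
    draws <- samples$effect
    effect_name <- samples$effect_name
  } else if (is.numeric(samples)) {
    draws <- samples
    effect_name <- "effect"
  } else {
    stop("`samples` must be posterior_samples or a numeric vector",
         call. = FALSE)
  }
  if (!is.numeric(cutpoints) || length(cutpoints) < 1L ||
      any(!is.finite(cutpoints)) || any(cutpoints <= 0) ||
      is.unsorted(cutpoints, strictly = TRUE))
    stop("`cutpoints` must be strictly increasing positive numbers",
         call. = FALSE)
  if (length(draws) < 1000)
    warning(sprintf("only %d draws: threshold probabilities carry visible Monte Carlo error",
                    length(draws)), call. = FALSE)
  if (mode == "exceedance") {
    probabilities <- vapply(cutpoints, function(ct) mean(draws > ct),
                            numeric(1))
    labels <- sprintf(">%g", cutpoints)
  } else {
    cell <- findInterval(draws, cutpoints)  # 0..length(cutpoints)
    probabilities <- tabulate(cell + 1L,
                              nbins = length(cutpoints) + 1L) / length(draws)
    labels <- c(sprintf("<%g", cutpoints[1]),
                if (length(cutpoints) > 1)
                  sprintf("%g-%g", cutpoints[-length(cutpoints)],
                          cutpoints[-1]),
                sprintf(">%g", cutpoints[length(cutpoints)]))
  }
  structure(list(mode = mode, cutpoints = cutpoints,
                 probabilities = probabilities, labels = labels,
                 effect_name = effect_name, n_draws = length(draws)),
            class = "threshold_table")
}

#' @export
print.threshold_table <- function(x, digits = if (x$mode == "exceedance") 2 else 1,
                                  ...) {
  pct <- sprintf(paste0("%.", digits, "f%%"), 100 * x$probabilities)
  cat(sprintf("Posterior probability of %s (%s mode, %d draws)\n",
              x$effect_name, x$mode, x$n_draws))
  out <- format(rbind(x$labels, pct), justify = "right")
  cat(paste(apply(out, 1, paste, collapse = "  "), collapse = "\n"), "\n")
  invisible(x)
}
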