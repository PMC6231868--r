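#' Per-subject dataset of a two-arm trial
#'
#' Holds one record per respondent with the randomized arm and the primary
#' outcome: a 0/1 indicator (e.g. abstinent / not abstinent) for binary
#' trials, or a non-negative whole count (e.g. standard drinks per week)
#' for count trials.  Both arms must be present and non-empty.
#'
#' @param arm Character or factor vector with values `"control"` and
#'   `"intervention"`.
#' @param outcome Numeric vector: 0/1 for `outcome_type = "binary"`,
#'   non-negative whole numbers for `outcome_type = "count"`.
#' @param outcome_type `"binary"` or `"count"`.
#' @return A data frame of class `trial_dataset` with columns `arm`
#'   (factor, levels control/intervention) and `outcome`, and attribute
#'   `outcome_type`.
#' @examples
#' trial_dataset(c("control", "control", "intervention", "intervention"),
#'               c(0, 1, 1, 1), "binary")
#' @export
trial_dataset <- function(arm, outcome, outcome_type = c("binary", "count")) {
  outcome_type <- match.arg(outcome_type)
  arm <- as.character(arm)
  bad <- which(!arm %in% c("control", "intervention"))
  if (length(bad))
    stop(sprintf("row %d: arm must be 'control' or 'intervention' (got '%s')",
                 bad[1], arm[bad[1]]), call. = FALSE)
  if (length(arm) != length(outcome))
    stop("`arm` and `outcome` must have the same length", call. = FALSE)
  bad <- which(!is_whole(outcome) | outcome < 0)
  if (length(bad))
    stop(sprintf("row %d: outcome must be a non-negative whole number",
                 bad[1]), call. = FALSE)
  if (outcome_type == "binary" && any(outcome > 1)) {
    bad <- which(outcome > 1)
    stop(sprintf("row %d: binary outcome must be 0 or 1", bad[1]),
         call. = FALSE)
  }
  arm <- factor(arm, levels = c("control", "intervention"))
  if (any(tabulate(arm, 2L) == 0L))
    stop("both arms must be present and non-empty", call. = FALSE)
  structure(data.frame(arm = arm, outcome = as.numeric(round(outcome))),
            outcome_type = outcome_type,
            class = c("trial_dataset", "data.frame"))
}

#' @export
print.trial_dataset <- function(x, ...) {
  n <- table(x$arm)
  cat(sprintf("Two-arm %s trial dataset: %d control, %d intervention\n",
              attr(x, "outcome_type"), n[["control"]], n[["intervention"]]))
  invisible(x)
}

outcome_type <- function(data) attr(data, "outcome_type")

# Per-arm sufficient statistics for a binary dataset.
arm_counts <- function(data) {
  stopifnot(inherits(data, "trial_dataset"),
            outcome_type(data) == "binary")
  ctrl <- data$outcome[data$arm == "control"]
  intv <- data$outcome[data$arm == "intervention"]
  list(s_c = sum(ctrl), n_c = length(ctrl),
       s_i = sum(intv), n_i = length(intv))
}

# Outcome vectors per arm for count datasets.
arm_outcomes <- function(data) {
  list(control = data$outcome[data$arm == "control"],
       intervention = data$outcome[data$arm == "intervention"])
}

#' Read a two-arm trial dataset from CSV
#'
#' Expects a header `arm,outcome` with arm values exactly `control` /
#' `intervention`.  The outcome type is inferred (all outcomes in \{0, 1\}
#' gives binary) unless given explicitly.  Malformed rows are reported by
#' their row number.
#'
#' @param path Path to a CSV file.
#' @param outcome_type `"binary"`, `"count"`, or `NULL` to infer.
#' @return A [trial_dataset()].
#' @export
read_trial_csv <- function(path, outcome_type = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("arm", "outcome") %in% names(df)))
    stop("CSV must have columns `arm` and `outcome`", call. = FALSE)
  if (!is.numeric(df$outcome)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$outcome))))[1]
    stop(sprintf("row %d: outcome '%s' is not numeric", bad,
                 df$outcome[bad]), call. = FALSE)
  }
  if (is.null(outcome_type))
    outcome_type <- if (all(df$outcome %in% c(0, 1))) "binary" else "count"
  trial_dataset(df$arm, df$outcome, outcome_type)
}

#' Write a two-arm trial dataset to CSV
#'
#' Writes the standard `arm,outcome` layout read back by
#' [read_trial_csv()].
#'
#' @param data A [trial_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(data, path) {
  stopifnot(inherits(data, "trial_dataset"))
  utils::write.csv(data.frame(arm = as.character(data$arm),
                              outcome = data$outcome),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a binary trial dataset from per-arm summary counts
#'
#' Expands `{control: successes/trials, intervention: successes/trials}`
#' summaries into the per-subject form used by the model fitters.
#'
#' @param control,intervention [binomial_count()] objects (or
#'   `c(successes, trials)` pairs).
#' @return A binary [trial_dataset()].
#' @export
trial_from_counts <- function(control, intervention) {
  control <- as_binomial_count(control)
  intervention <- as_binomial_count(intervention)
  trial_dataset(
    rep(c("control", "intervention"),
        c(control$trials, intervention$trials)),
    c(rep(1:0, c(control$successes, control$trials - control$successes)),
      rep(1:0, c(intervention$successes,
                 intervention$trials - intervention$successes))),
    "binary")
}
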