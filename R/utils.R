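# Internal numeric helpers shared across modules.

# Composite trapezoid rule on an ordered grid.
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Running trapezoid integral; element i is the integral up to x[i].
cum_trapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2))
}

# Overflow-safe log(1 + exp(x)); for x >= 33.3 the result equals x in
# double precision.
log1pexp <- function(x) {
  out <- x
  small <- x < 18
  out[small] <- log1p(exp(x[small]))
  mid <- !small & x < 33.3
  out[mid] <- x[mid] + exp(-x[mid])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_whole <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}

check_scalar_prob <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (open && (x <= 0 || x >= 1))
    stop(sprintf("`%s` must lie strictly between 0 and 1", name), call. = FALSE)
  if (!open && (x < 0 || x > 1))
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  invisible(x)
}

check_seed <- function(seed) {
  if (missing(seed) || is.null(seed) || !is.numeric(seed) ||
      length(seed) != 1L || !is.finite(seed) || !is_whole(seed))
    stop("a single integer `seed` is required", call. = FALSE)
  as.integer(seed)
}
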