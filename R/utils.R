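# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the previous
#' RNG state afterwards so callers do not perturb the session stream.
#' A `NULL` seed leaves the RNG untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Total overlap (Myr) of lineage intervals [te, ts] with the age interval
# [young, old]; ages in Ma, old > young.
interval_overlap <- function(ts, te, old, young) {
  pmax(0, pmin(ts, old) - pmax(te, young))
}

# Cumulative trapezoidal integral of y over a grid of strictly decreasing
# ages, returned as the integral from the oldest grid point down to each age
# (non-negative, increasing toward the present).
cum_trapz_desc <- function(age, y) {
  n <- length(age)
  seg <- -diff(age) * (y[-1] + y[-n]) / 2
  c(0, cumsum(seg))
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  }
}
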