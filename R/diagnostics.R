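# MCMC diagnostics: effective sample size, HPD intervals, replicate pooling.

#' Effective sample size of an MCMC chain
#'
#' Autocorrelation-time estimate using Geyer's initial positive sequence:
#' autocorrelations are summed in consecutive pairs until a pair sum goes
#' non-positive. A constant chain is reported as its own length with a
#' warning.
#'
#' @param x numeric chain (>= 2 samples).
#' @return estimated effective sample size.
#' @export
ess <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("ess needs >= 2 samples")
  if (stats::var(x) == 0) {
    warning("constant chain; ESS reported as chain length")
    return(n)
  }
  lag_max <- min(n - 1L, 1000L)
  rho <- stats::acf(x, lag.max = lag_max, plot = FALSE,
                    demean = TRUE)$acf[-1]
  s <- 0
  m <- 1L
  while (m <= length(rho)) {
    g <- rho[m] + if (m + 1L <= length(rho)) rho[m + 1L] else 0
    if (g <= 0) break
    s <- s + g
    m <- m + 2L
  }
  max(1, min(n, n / (1 + 2 * s)))
}

#' Highest posterior density interval
#'
#' Shortest interval containing the requested posterior mass, computed
#' from the empirical sample (for symmetric unimodal posteriors this
#' coincides with the equal-tail interval).
#'
#' @param x posterior sample (>= 2 values).
#' @param mass probability mass (default 0.95).
#' @return numeric `c(lower, upper)`.
#' @export
hpd <- function(x, mass = 0.95) {
  stopifnot(length(x) >= 2L)
  stopifnot_scalar_prob(mass, "mass")
  x <- sort(as.numeric(x))
  n <- length(x)
  m <- max(1L, ceiling(mass * n))
  if (m >= n) return(c(x[1L], x[n]))
  w <- x[(m + 1L):n] - x[1L:(n - m)]
  i <- which.min(w)
  c(x[i], x[i + m])
}

#' Pool posterior rate grids across age-randomized replicates
#'
#' Stacks the (post burn-in) posterior samples of several [rjmcmc_rates()]
#' runs on their common age grid and recomputes the pooled mean and 95%
#' HPD envelope, the standard way of propagating stage-level age
#' uncertainty into the final rate trajectories.
#'
#' @param runs list of results from [rjmcmc_rates()] sharing one grid.
#' @param mass HPD mass (default 0.95).
#' @return list with `grid` and, per rate, a data frame `age`, `mean`,
#'   `lo`, `hi`.
#' @export
combine_replicates <- function(runs, mass = 0.95) {
  stopifnot(length(runs) >= 1L)
  grid <- runs[[1L]]$grid
  for (r in runs) {
    if (!isTRUE(all.equal(r$grid, grid))) stop("runs must share one age grid")
  }
  pool <- function(field) {
    s <- do.call(rbind, lapply(runs, function(r) r[[field]]$samples))
    data.frame(
      age = grid,
      mean = colMeans(s),
      lo = apply(s, 2, function(v) hpd(v, mass)[1]),
      hi = apply(s, 2, function(v) hpd(v, mass)[2])
    )
  }
  list(grid = grid, lambda = pool("lambda"), mu = pool("mu"))
}
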