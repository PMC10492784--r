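# Diversity trajectories from Ts/Te and discrete-bin (boundary-crosser)
# rate estimators used as cross-checks on the continuous Bayesian rates.

#' Lineage-through-time diversity
#'
#' Diversity at age `t` is the number of lineages whose
#' `(Ts, Te)` interval covers it: `#\{i : Ts_i >= t > Te_i\}`. With
#' several age-randomized replicates the curves are pooled into a mean,
#' median and range envelope.
#'
#' @param times a times data frame (`ts`, `te`) or a list of them (one
#'   per replicate).
#' @param grid ages (Ma) at which to evaluate diversity.
#' @return list with `grid`, `counts` (replicate x grid integer matrix),
#'   `mean`, `median`, `lo`, `hi` (pointwise replicate range).
#' @export
ltt_diversity <- function(times, grid) {
  if (is.data.frame(times)) times <- list(times)
  counts <- t(vapply(times, function(tt) {
    vapply(grid, function(g) sum(tt$ts >= g & g > tt$te), numeric(1))
  }, numeric(length(grid))))
  list(grid = grid, counts = counts,
       mean = colMeans(counts),
       median = apply(counts, 2, stats::median),
       lo = apply(counts, 2, min),
       hi = apply(counts, 2, max))
}

#' Boundary-crosser tallies per time bin
#'
#' Counts, per bin, the four boundary-crosser classes used by the
#' per-capita rate estimators: `n_bt` (cross bottom and top), `n_bl`
#' (bottom crossers last seen in the bin), `n_ft` (first seen in the bin,
#' cross the top) and `n_fl` (confined to the bin), plus sampled-in-bin
#' richness and three-timer tallies. Called on a times data frame
#' (`ts`/`te`), ranges are the corrected durations and sampling is
#' complete by construction; called on occurrence records, ranges are
#' range-through first/last appearances of midpoint ages and
#' sampled-in-bin reflects actual sampling.
#'
#' @param x times data frame (`ts`, `te`) or occurrence records
#'   (`genus`, `max_ma`, `min_ma`).
#' @param bins data frame `bin`, `max_ma`, `min_ma`, oldest first,
#'   tiling the window.
#' @return data frame, one row per bin, with the tallies above.
#' @export
bin_counts <- function(x, bins) {
  if (any(bins$max_ma <= bins$min_ma)) stop("bins must have positive duration")
  if (!is.null(x$ts)) {
    fad <- x$ts
    lad <- x$te
    mids <- NULL
    gi <- seq_along(fad)
  } else {
    mid <- (x$max_ma + x$min_ma) / 2
    taxa <- unique(x$genus)
    gi <- match(x$genus, taxa)
    fad <- as.numeric(tapply(mid, gi, max))
    lad <- as.numeric(tapply(mid, gi, min))
    mids <- mid
  }
  nb <- nrow(bins)
  ng <- length(fad)
  # presence (sampling) matrix
  pres <- matrix(FALSE, ng, nb)
  for (j in seq_len(nb)) {
    if (is.null(mids)) {
      pres[, j] <- fad > bins$min_ma[j] & lad < bins$max_ma[j]
    } else {
      inb <- mids <= bins$max_ma[j] & mids > bins$min_ma[j]
      pres[unique(gi[inb]), j] <- TRUE
    }
  }
  out <- data.frame(bin = bins$bin, max_ma = bins$max_ma,
                    min_ma = bins$min_ma)
  for (j in seq_len(nb)) {
    b_old <- bins$max_ma[j]
    b_yng <- bins$min_ma[j]
    cb <- fad >= b_old & lad < b_old      # alive at the bottom boundary
    ct <- fad >= b_yng & lad < b_yng      # alive at the top boundary
    ov <- fad > b_yng & lad < b_old       # range overlaps the bin
    out$n_bt[j] <- sum(cb & ct)
    out$n_bl[j] <- sum(cb & !ct)
    out$n_ft[j] <- sum(ct & !cb)
    out$n_fl[j] <- sum(ov & !cb & !ct)
    out$sib[j] <- sum(pres[, j])
    out$three_t[j] <- if (j > 1 && j < nb)
      sum(pres[, j - 1] & pres[, j] & pres[, j + 1]) else NA_integer_
    out$part_t[j] <- if (j > 1 && j < nb)
      sum(pres[, j - 1] & !pres[, j] & pres[, j + 1]) else NA_integer_
  }
  out
}

#' Per-capita origination and extinction rates
#'
#' Boundary-crosser estimators per bin of duration \eqn{\Delta t}:
#' \deqn{p = -\log(n_{bt}/(n_{bt}+n_{ft}))/\Delta t, \quad
#'       q = -\log(n_{bt}/(n_{bt}+n_{bl}))/\Delta t.}
#' Bins with no through-crossers (`n_bt = 0`) are reported as missing,
#' never as zero.
#'
#' @param counts output of [bin_counts()].
#' @return `counts` with columns `p` and `q` added (per-Myr rates).
#' @export
per_capita_rates <- function(counts) {
  dt <- counts$max_ma - counts$min_ma
  if (any(dt <= 0)) stop("zero-duration bin")
  ok <- counts$n_bt > 0
  counts$p <- ifelse(ok, -log(counts$n_bt / (counts$n_bt + counts$n_ft)) / dt,
                     NA_real_)
  counts$q <- ifelse(ok, -log(counts$n_bt / (counts$n_bt + counts$n_bl)) / dt,
                     NA_real_)
  counts
}

#' Three-timer sampling completeness and corrected richness
#'
#' Completeness is pooled across the dataset as
#' \eqn{3T/(3T+PT)}; corrected sampled-in-bin richness divides each bin's
#' richness by it. Missing when no three-timer information exists.
#'
#' @param counts output of [bin_counts()] (needs >= 3 consecutive bins).
#' @return list with `completeness` (scalar) and `corrected` (per-bin
#'   corrected richness).
#' @export
three_timer_completeness <- function(counts) {
  if (nrow(counts) < 3L) stop("need >= 3 consecutive bins")
  t3 <- sum(counts$three_t, na.rm = TRUE)
  pt <- sum(counts$part_t, na.rm = TRUE)
  comp <- if (t3 + pt == 0) NA_real_ else t3 / (t3 + pt)
  list(completeness = comp, corrected = counts$sib / comp)
}

#' Correlation between two binned rate series
#'
#' Pairwise-complete Pearson or Spearman correlation on bin-aligned
#' series after trimming edge bins, where boundary-crosser rates are
#' biased by edge effects.
#'
#' @param series_a,series_b numeric vectors on the same bins.
#' @param drop_edge_bins bins removed from each end (default 2).
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `estimate`, `p_value`, `n` (points used).
#' @export
rate_correlation <- function(series_a, series_b, drop_edge_bins = 2,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(series_a) == length(series_b))
  n <- length(series_a)
  keep <- seq_len(n) > drop_edge_bins & seq_len(n) <= n - drop_edge_bins
  a <- series_a[keep]
  b <- series_b[keep]
  ok <- stats::complete.cases(a, b)
  if (sum(ok) < 5L) stop("fewer than 5 overlapping bins after trimming")
  ct <- suppressWarnings(stats::cor.test(a[ok], b[ok], method = method))
  list(estimate = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}
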