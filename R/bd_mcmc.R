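# Two-step Bayesian core: (1) Gibbs sampling of preservation-corrected
# origination/extinction times; (2) reversible-jump MCMC over
# piecewise-constant origination and extinction rate trajectories at
# fixed times.

#' MCMC run settings
#'
#' @param n_iter chain length (iterations).
#' @param n_samples posterior samples to save (default 1000).
#' @param burnin burn-in fraction in `[0, 1)` (default 0.10).
#' @param rng_seed integer seed; a fixed seed gives identical chains.
#' @param ess_threshold minimum effective sample size for a run to be
#'   considered converged (default 200); non-converged runs are returned
#'   flagged so the caller can extend the chain.
#' @return object of class `mcmc_run`.
#' @export
mcmc_run <- function(n_iter = 20000, n_samples = 1000, burnin = 0.10,
                     rng_seed = NULL, ess_threshold = 200) {
  stopifnot(burnin >= 0, burnin < 1, n_samples >= 2, n_iter > n_samples)
  structure(list(n_iter = as.integer(n_iter),
                 n_samples = as.integer(n_samples),
                 burnin = burnin, rng_seed = rng_seed,
                 ess_threshold = ess_threshold),
            class = "mcmc_run")
}

# truncated exponential draw on [0, upper]
rtrunc_exp <- function(n, rate, upper) {
  u <- stats::runif(n)
  ifelse(rate * upper < 1e-12,
         u * upper,
         -log1p(-u * (-expm1(-rate * upper))) / rate)
}

#' Gibbs sampling of preservation-corrected origination/extinction times
#'
#' Samples each taxon's `Ts` and `Te` from their full conditionals given
#' the occurrence record: the extension of `Ts` beyond the oldest
#' occurrence (and of `Te` below the youngest) is a truncated exponential
#' with rate `q + mu` -- the preservation rate local to the range end plus
#' the extinction-rate prior -- truncated at the window edge. Preservation
#' rates are updated by conjugate gamma draws under the gamma(shape,
#' rate) prior; when the prior rate is 0 the rate hyperparameter is given
#' a vague gamma hyperprior and sampled alongside `q`.
#'
#' @param occurrences data frame with a taxon id column and `age` (one
#'   age-resolved replicate; every taxon needs >= 1 occurrence).
#' @param model a [preservation_model()] of kind HPP or TPP (the
#'   within-lineage NHPP profile has no conjugate time update and is not
#'   supported here).
#' @param window `c(older, younger)` analysis window (Ma) truncating the
#'   extensions.
#' @param mcmc an [mcmc_run()].
#' @param bd_mu extinction-rate prior entering the extension rate.
#' @param extant_taxa taxa known to survive the window (their `Te` is
#'   pinned to the younger edge and flagged non-extinct).
#' @param fix_q keep `model$q` fixed instead of sampling it.
#' @return list with `times` (posterior mean `ts`, `te`, `extinct` per
#'   taxon), `ts_samples`, `te_samples`, `q_samples`, `ess` (per-block
#'   ESS), and `converged`.
#' @export
sample_times <- function(occurrences, model, window, mcmc = mcmc_run(),
                         bd_mu = 0.1, extant_taxa = NULL, fix_q = FALSE) {
  ids <- taxon_col(occurrences)
  age <- occurrences$age
  taxa <- unique(ids)
  n <- length(taxa)
  gi <- match(ids, taxa)
  x_old <- as.numeric(tapply(age, gi, max))
  x_young <- as.numeric(tapply(age, gi, min))
  n_occ <- tabulate(gi, n)
  extant <- taxa %in% (extant_taxa %||% character(0))
  if (model$kind == "NHPP") stop("sample_times supports HPP and TPP models")
  edges <- if (model$kind == "TPP") model$bin_edges else window
  k <- length(edges) - 1L
  # occurrence counts per bin are fixed by the data
  bj <- findInterval(-age, -edges, rightmost.closed = TRUE)
  bj[bj < 1L] <- 1L
  bj[bj > k] <- k
  n_k <- tabulate(bj, k)
  shape <- model$gamma_shape
  est_beta <- model$gamma_rate == 0 && !fix_q
  with_seed(mcmc$rng_seed, {
    q <- if (!is.null(model$q)) rep_len(model$q, k) else
      rep(sum(n_occ) / max(sum(x_old - x_young), 1), k)
    beta <- if (est_beta) 1 else max(model$gamma_rate, 1e-8)
    ts <- x_old
    te <- ifelse(extant, window[2], x_young)
    save_at <- unique(round(seq(max(2, mcmc$burnin * mcmc$n_iter + 1),
                                mcmc$n_iter,
                                length.out = min(mcmc$n_samples, mcmc$n_iter))))
    ts_s <- matrix(NA_real_, length(save_at), n)
    te_s <- matrix(NA_real_, length(save_at), n)
    q_s <- matrix(NA_real_, length(save_at), k)
    si <- 1L
    q_at <- function(a) {
      i <- findInterval(-a, -edges, rightmost.closed = TRUE)
      i[i < 1L] <- 1L
      i[i > k] <- k
      q[i]
    }
    for (it in seq_len(mcmc$n_iter)) {
      ts <- x_old + rtrunc_exp(n, q_at(x_old) + bd_mu, window[1] - x_old)
      d_e <- rtrunc_exp(n, q_at(x_young) + bd_mu, x_young - window[2])
      te <- ifelse(extant, window[2], x_young - d_e)
      if (!fix_q) {
        t_k <- vapply(seq_len(k), function(j) {
          sum(interval_overlap(ts, te, edges[j], edges[j + 1L]))
        }, numeric(1))
        q <- stats::rgamma(k, shape + n_k, beta + t_k)
        if (est_beta) beta <- stats::rgamma(1, 1 + shape * k, 0.1 + sum(q))
      }
      if (si <= length(save_at) && it == save_at[si]) {
        ts_s[si, ] <- ts
        te_s[si, ] <- te
        q_s[si, ] <- q
        si <- si + 1L
      }
    }
    ess_vals <- c(ts_mean = ess(rowMeans(ts_s)),
                  q_mean = if (fix_q) NA_real_ else ess(rowMeans(q_s)))
    ess_vals <- ess_vals[!is.na(ess_vals)]
    list(
      times = data.frame(taxon = taxa, ts = colMeans(ts_s),
                         te = colMeans(te_s), extinct = !extant,
                         stringsAsFactors = FALSE),
      ts_samples = ts_s, te_samples = te_s, q_samples = q_s,
      bin_edges = edges,
      ess = ess_vals,
      converged = all(ess_vals > mcmc$ess_threshold)
    )
  })
}

#' Reversible-jump MCMC over piecewise-constant rate trajectories
#'
#' At fixed origination/extinction times, samples the number, placement
#' and heights of rate shifts in \eqn{\lambda(t)} and \eqn{\mu(t)}
#' independently. Moves: add a shift (new time uniform in the window, new
#' segment rate drawn from the gamma prior), remove a shift, slide a
#' shift time (uniform window of `move_window` Myr), and rescale a
#' segment rate (multiplicative log-normal). The shift count carries a
#' Poisson prior, segment rates i.i.d. gamma priors, and acceptance uses
#' the exact birth--death log-likelihood.
#'
#' @param times data frame with `ts`, `te`, `extinct` (posterior means
#'   from [sample_times()], or ground truth in simulations).
#' @param window `c(older, younger)` analysis window (Ma).
#' @param mcmc an [mcmc_run()].
#' @param shift_prior_mean Poisson prior mean on the number of shifts per
#'   rate vector (default 1).
#' @param rate_shape,rate_rate gamma prior on segment rates.
#' @param grid_step spacing (Myr) of the posterior summary grid.
#' @param move_window width (Myr) of the sliding shift-time proposal.
#' @param use_likelihood set `FALSE` to sample the prior only (used to
#'   validate the sampler against the Poisson shift-count prior).
#' @return list with per-rate components (`grid`, `mean`, `lo`, `hi`,
#'   `samples` matrix, `k_samples`, `shift_samples`), `logl_samples`,
#'   `ess`, and `converged`.
#' @export
rjmcmc_rates <- function(times, window, mcmc = mcmc_run(),
                         shift_prior_mean = 1, rate_shape = 2,
                         rate_rate = 5, grid_step = 0.5, move_window = 5,
                         use_likelihood = TRUE) {
  ts <- pmin(times$ts, window[1])
  te <- pmax(times$te, window[2])
  orig_ages <- times$ts[times$ts < window[1] & times$ts > window[2]]
  ext_ages <- times$te[times$extinct & times$te > window[2] &
                         times$te < window[1]]
  part_ll <- function(events, shifts, rates) {
    if (!use_likelihood) return(0)
    bd_part_loglik(events, ts, te, c(window[1], shifts, window[2]), rates)
  }
  span <- window[1] - window[2]
  grid <- seq(window[1], window[2], by = -grid_step)
  prior_r <- function(r) stats::dgamma(r, rate_shape, rate_rate, log = TRUE)

  run_chain <- function(events) {
    st <- list(shifts = numeric(0),
               rates = max(length(events), 1) / max(sum(ts - te), 1e-9))
    ll <- part_ll(events, st$shifts, st$rates)
    save_at <- unique(round(seq(max(2, mcmc$burnin * mcmc$n_iter + 1),
                                mcmc$n_iter,
                                length.out = mcmc$n_samples)))
    samp <- matrix(NA_real_, length(save_at), length(grid))
    k_s <- integer(length(save_at))
    ll_s <- numeric(length(save_at))
    shift_s <- vector("list", length(save_at))
    si <- 1L
    for (it in seq_len(mcmc$n_iter)) {
      k <- length(st$shifts)
      u <- stats::runif(1)
      if (u < 0.25) { # birth
        s_new <- stats::runif(1, window[2], window[1])
        r_new <- stats::rgamma(1, rate_shape, rate_rate)
        pos <- sum(st$shifts > s_new)
        shifts2 <- append(st$shifts, s_new, after = pos)
        rates2 <- append(st$rates, r_new, after = pos + 1L)
        ll2 <- part_ll(events, shifts2, rates2)
        if (log(stats::runif(1)) < ll2 - ll + log(shift_prior_mean / (k + 1))) {
          st <- list(shifts = shifts2, rates = rates2)
          ll <- ll2
        }
      } else if (u < 0.5) { # death
        if (k > 0L) {
          j <- if (k == 1L) 1L else sample.int(k, 1L)
          shifts2 <- st$shifts[-j]
          rates2 <- st$rates[-(j + 1L)]
          ll2 <- part_ll(events, shifts2, rates2)
          if (log(stats::runif(1)) < ll2 - ll + log(k / shift_prior_mean)) {
            st <- list(shifts = shifts2, rates = rates2)
            ll <- ll2
          }
        }
      } else if (u < 0.7) { # slide a shift time
        if (k > 0L) {
          j <- if (k == 1L) 1L else sample.int(k, 1L)
          s2 <- st$shifts[j] + stats::runif(1, -move_window / 2, move_window / 2)
          lo <- if (j < k) st$shifts[j + 1L] else window[2]
          hi <- if (j > 1L) st$shifts[j - 1L] else window[1]
          if (s2 > lo && s2 < hi) {
            shifts2 <- st$shifts
            shifts2[j] <- s2
            ll2 <- part_ll(events, shifts2, st$rates)
            if (log(stats::runif(1)) < ll2 - ll) {
              st$shifts <- shifts2
              ll <- ll2
            }
          }
        }
      } else { # rescale one segment rate
        j <- if (k == 0L) 1L else sample.int(k + 1L, 1L)
        r2 <- st$rates[j] * exp(stats::rnorm(1, 0, 0.3))
        rates2 <- st$rates
        rates2[j] <- r2
        ll2 <- part_ll(events, st$shifts, rates2)
        a <- ll2 - ll + prior_r(r2) - prior_r(st$rates[j]) +
          log(r2 / st$rates[j])
        if (log(stats::runif(1)) < a) {
          st$rates <- rates2
          ll <- ll2
        }
      }
      if (si <= length(save_at) && it == save_at[si]) {
        tr <- rate_trajectory(st$shifts, st$rates, window)
        samp[si, ] <- traj_rate_at(tr, grid)
        k_s[si] <- length(st$shifts)
        ll_s[si] <- ll
        shift_s[[si]] <- st$shifts
        si <- si + 1L
      }
    }
    list(samples = samp, k_samples = k_s, logl = ll_s,
         shift_samples = shift_s,
         mean = colMeans(samp),
         lo = apply(samp, 2, function(v) hpd(v)[1]),
         hi = apply(samp, 2, function(v) hpd(v)[2]))
  }

  with_seed(mcmc$rng_seed, {
    lam <- run_chain(orig_ages)
    mu <- run_chain(ext_ages)
    ess_vals <- c(lambda = ess(rowMeans(lam$samples)),
                  mu = ess(rowMeans(mu$samples)))
    list(grid = grid, lambda = lam, mu = mu,
         logl_samples = lam$logl + mu$logl,
         ess = ess_vals,
         converged = all(ess_vals > mcmc$ess_threshold))
  })
}

#' Impute lineages that left no fossil record
#'
#' Rate estimation from sampled lineages alone is biased downward:
#' lineages that died young are the least likely to be sampled at all,
#' so their origination and (especially) extinction events are missing
#' from the times table. Under the fitted preservation model the
#' missingness is quantifiable -- a lineage of duration `d` goes
#' unsampled with probability `exp(-q d)` -- and the missing lineages
#' can be imputed: with exponential lifetimes their expected number is
#' `n * p / (1 - p)` with `p = mu / (q + mu)`, and their durations
#' follow an Exponential(q + mu) law. This function appends that many
#' deterministic (quantile-spaced) ghost lineages, their originations
#' spread over the observed origination quantiles, and iterates the
#' extinction-rate estimate so the imputation is self-consistent.
#'
#' @param times data frame with `ts`, `te`, `extinct` (and optionally a
#'   taxon id column) for the sampled lineages.
#' @param q preservation rate per lineage-Myr (e.g. the posterior mean
#'   from [sample_times()]).
#' @param window `c(older, younger)` sampling window (Ma).
#' @param mu fixed extinction rate; `NULL` (default) estimates it from
#'   `times` and iterates.
#' @return `times` with ghost rows appended (taxon ids `unsampled_*`);
#'   unchanged when the expected missing count rounds to zero.
#' @export
augment_unsampled <- function(times, q, window, mu = NULL) {
  dur <- times$ts - times$te
  L <- sum(dur)
  if (L <= 0 || q <= 0) return(times)
  mu_hat <- mu %||% (sum(times$extinct) / L)
  if (mu_hat <= 0) return(times)
  M <- 0L
  d_g <- numeric(0)
  for (i in 1:3) {
    p <- mu_hat / (q + mu_hat)
    M <- as.integer(round(nrow(times) * p / (1 - p)))
    if (M < 1L) return(times)
    d_g <- stats::qexp(stats::ppoints(M), q + mu_hat)
    if (is.null(mu)) {
      mu_hat <- (sum(times$extinct) + M) / (L + sum(d_g))
    }
  }
  ts_in <- times$ts[times$ts < window[1] & times$ts > window[2]]
  if (length(ts_in) < 2L) return(times)
  ts_g <- stats::quantile(ts_in, stats::ppoints(M), names = FALSE)
  te_g <- pmax(ts_g - d_g, window[2])
  ghosts <- data.frame(ts = ts_g, te = te_g,
                       extinct = ts_g - d_g > window[2])
  if (!is.null(times$taxon)) {
    ghosts$taxon <- paste0("unsampled_", seq_len(M))
  }
  rbind(times[, names(ghosts)], ghosts)
}

#' Simulate a birth--death dataset conditioned on its size
#'
#' Draws from [simulate_bd()] under `config`, redrawing with a shifted
#' seed until the total lineage count falls in `n_range` (at most 20
#' attempts). Recovery experiments use this to hold the dataset at the
#' intended scale of a few hundred lineages, rejecting both near-total
#' extinctions and runaway radiations.
#'
#' @param rng_seed integer seed.
#' @param config a [sim_config()].
#' @param n_range acceptable total lineage count.
#' @return list with `history` and the `config` actually used.
#' @export
simulate_bd_dataset <- function(rng_seed, config = sim_config(n_seed = 6),
                                n_range = c(120, 400)) {
  for (try in 0:19) {
    cfg <- config
    cfg$rng_seed <- rng_seed + 104729L * try
    h <- simulate_bd(cfg)
    if (nrow(h$lineages) >= n_range[1] && nrow(h$lineages) <= n_range[2]) {
      return(list(history = h, config = cfg))
    }
  }
  stop("no acceptable dataset size in 20 attempts; widen n_range")
}
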