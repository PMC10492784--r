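# paleodiv

Bayesian estimation of origination and extinction dynamics from
genus-level fossil occurrence tables, with the supporting machinery a
full analysis needs: occurrence curation, Poisson preservation models,
reversible-jump detection of rate shifts, diversity reconstruction,
multivariate driver analysis under horseshoe shrinkage, and
palaeobiogeographic regionalization with spatial standardization. A
synthetic fossil-record generator with known ground truth makes every
stage testable without touching an external database.

## Who it is for

Palaeobiologists working with Paleobiology-Database-style occurrence
tables (taxon, collection, stage-resolved age interval, lithology,
palaeocoordinates) who want preservation-corrected diversification
rates rather than raw range counts, and who want the intermediate
decisions — what was cleaned and why, whether chains converged, how
rates respond to putative drivers — to be auditable.

## The model in brief

Occurrences of a genus are a Poisson process with preservation rate
*q(t)* (homogeneous, within-lineage modulated, or piecewise-constant
between stage boundaries) along its latent lifespan (*Ts*, *Te*).
Lineages originate at per-capita rate *λ(t)* and die at *μ(t)*. The
analysis is two-step:

1. `sample_times()` draws the preservation-corrected *Ts* and *Te* of
   each genus by Gibbs sampling: the extension beyond the observed
   range ends is truncated-exponential with rate *q + μ*, and *q* is
   updated conjugately under a gamma prior (shape 1.5, rate estimated).
2. `rjmcmc_rates()` samples piecewise-constant *λ(t)* and *μ(t)* at the
   fixed times by reversible-jump MCMC (Poisson prior on the number of
   shifts, gamma priors on segment rates, exact birth–death likelihood
   with the lineage-time integral computed in closed form).

Stage-level age uncertainty is propagated by analysing age-randomized
replicates (`randomize_ages()`) and pooling their posteriors
(`combine_replicates()`). The multivariate birth–death model
(`fit_mbd()`) ties log rates to time-continuous predictors,
*λ(t) = λ₀ exp(Σⱼ Gⱼ vⱼ(t))*, with horseshoe priors on the *G*s; a
predictor is reported as signal when its shrinkage weight
*w = E[1 − 1/(1 + τ²κ²)]* exceeds 0.5. Spatial structure is handled by
hexagonal binning, modified-Forbes dissimilarity, PAM plus network
community detection (`regionalize()`), and minimum-spanning-tree
standardization of per-bin spatial footprints (`mst_standardize()`).

## Worked example

```r
library(paleodiv)

cfg  <- sim_config(rng_seed = 7)            # lambda 0.2, mu 0.1, q 1.0
h    <- simulate_bd(cfg)                    # ground-truth history
occ  <- simulate_preservation(h, cfg)       # fossil occurrences
occ$taxon <- occ$lineage
st   <- sample_times(occ, preservation_model("HPP"),
                     c(cfg$t_start, cfg$t_end),
                     mcmc = mcmc_run(n_iter = 4000, rng_seed = 1),
                     extant_taxa = h$lineages$lineage[!h$lineages$extinct])
run  <- rjmcmc_rates(st$times, c(273.0, 247.2),
                     mcmc = mcmc_run(rng_seed = 2))
mid  <- which.min(abs(run$grid - 260))
round(c(lambda = run$lambda$mean[mid], mu = run$mu$mean[mid]), 3)
#> lambda     mu
#>  0.184  0.081
hpd(run$lambda$samples[, mid])
#> [1] 0.1568948 0.2131555
table(run$mu$k_samples)
#>   0   1   2   3
#> 793 188  18   1
```

The posterior mean origination rate at 260 Ma is 0.184 per
lineage-Myr with a 95% HPD of [0.157, 0.213] — the generating value of
0.2 sits inside it — and the extinction-rate posterior puts its mode at
zero shifts, as it should for data simulated at constant rates. (Rates
from sampled lineages alone run a little low because lineages that
never fossilize are the short-lived ones; `augment_unsampled()` applies
the model-based correction when an unbiased point estimate matters.)

A full run — simulate or ingest, curate, randomize ages, times, rates,
diversity, optional driver analysis, spatial standardization — is one
call:

```r
report <- run_pipeline(list(output_dir = "run1", seed = 1))
```

which persists every intermediate (occurrence table, rejection log,
times, rate grids, diversity, regional assignments, MST audit) as
CSV/TSV under `run1/`. A thin command-line wrapper with the same
stages lives at `inst/scripts/paleodiv.R`.

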