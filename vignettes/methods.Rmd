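---
title: "Models and design choices in paleodiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in paleodiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(paleodiv)
```

paleodiv estimates diversification dynamics from genus-level fossil
occurrence tables. This vignette explains the models it implements, the
conventions and tunables that matter, what the synthetic-data generator
does and does not emulate, and the places where the design was
genuinely open and a choice had to be made.

## Conventions

Ages are in Ma before present (larger = older). All intervals are
half-open `[older, younger)`, so an event exactly at a boundary belongs
to the older-starting interval. Rates are events per lineage per Myr.
The packaged stage table covers the Kasimovian through the Valanginian
with GTS2020-style boundaries; Permian–Jurassic analyses use stage
boundaries as preservation-shift times and longer-span analyses use
series boundaries, both derived with `stage_boundaries()`. Substages
are early/late halves of equal duration.

## Occurrence curation

`clean_occurrences()` applies deterministic rules, each logged per row:
ambiguous genus names are dropped (open species names like "sp." do
not make a genus ambiguous); terrestrial records are dropped;
open-nomenclature qualifiers (`cf.`, `aff.`, `?`, `informal`,
`ex. gr.`) drop a row only when the primary and accepted genus names
agree — a differing accepted name records a reassignment and is kept;
rows with age spans strictly over 10 Myr are dropped unless they are
resolved to a single international stage (so a ~15 Myr Guadalupian row
falls while a ~18 Myr Norian row stays). "International stage" is a
boolean resolved from the stage dictionary, never inferred from the
span itself.

`flag_range_outliers()` uses empirical quantiles of each genus's
occurrence midpoint ages: occurrences outside the central 90% interval
are flagged. Quantiles were chosen over kernel density because they
are transparent, deterministic, and directly testable with
order-statistics arguments; single-occurrence genera are never
flagged. The function flags — it never adjudicates reliability, which
in real workflows involves literature checking.

`randomize_ages()` propagates stage-level age uncertainty: per
replicate, every collection receives one uniform draw from its age
interval and all occurrences of the collection share that coeval age.
Ten replicates is the default; downstream posteriors are pooled with
`combine_replicates()` after each run's burn-in.

## Preservation models

Three Poisson flavours are implemented behind one interface
(`preservation_model()`): HPP (one rate), NHPP (one rate modulating a
within-lineage profile), and TPP (piecewise-constant rates between
stage or series boundaries). All likelihoods condition on each sampled
lineage having at least one occurrence, via `-log(1 - exp(-Q_i))` with
`Q_i` the integrated intensity over the lineage's duration.

The NHPP's within-lineage profile is a symmetric Beta(2, 2) hat over
`[Te, Ts]` — sampling peaking mid-range — scaled so its integrated
intensity equals the HPP's. The upstream literature names this model
class without fixing a functional form; the Beta(2, 2) choice is a
modelling decision of this package and is deliberately isolated behind
the `preservation_model` interface so it can be swapped.

`select_preservation_model()` fits each candidate by maximum
likelihood at fixed times and ranks by AIC. The gamma prior on
preservation rates (shape 1.5) enters the Gibbs sampler, not the model
selection; a prior rate of 0 means the rate hyperparameter gets a
vague gamma hyperprior and is sampled together with `q`. Per-lineage
rate multipliers (gamma heterogeneity across lineages) are
intentionally not implemented: with Gibbs time sampling that model
class is prone to spurious convergence, and the package mirrors the
choice to drop it.

## The two-step Bayesian core

Estimating times and rates jointly is expensive at the scale of
hundreds of genera, so the package follows a two-step procedure.

**Step 1 — times.** `sample_times()` draws `Ts` and `Te` from their
full conditionals: the extension of `Ts` beyond the oldest occurrence
(and of `Te` below the youngest) is truncated-exponential with rate
`q + mu`, truncated at the window edge. The `exp(-q delta)` factor is
the probability of no fossils in the extension; the `exp(-mu delta)`
factor is the lifetime prior. Preservation rates update conjugately.
Taxa known to survive the window (`extant_taxa`) have `Te` pinned to
the young edge and are right-censored in the rate step. The q update
omits the at-least-one-occurrence conditioning, which makes this an
approximate posterior — the approximation error is negligible next to
the stage-level age uncertainty the replicates already carry.

**Step 2 — rates.** `rjmcmc_rates()` samples piecewise-constant
trajectories for origination and extinction independently at the fixed
(posterior-mean) times. Moves: add a shift (time uniform in the
window, new segment rate drawn from its gamma prior — with that
proposal the acceptance ratio reduces to the likelihood ratio times
`nu/(K+1)`, and the sampler exactly reproduces the Poisson(`nu`) shift
prior when the likelihood is switched off, which the test suite
checks); delete a shift; slide a shift inside a 5 Myr uniform window;
rescale a segment rate by a multiplicative log-normal step. The
birth–death log-likelihood is exact: event terms at origination and
extinction ages plus a lineage-time integral computed in closed form
from segment overlaps (verified against per-cell exact quadrature to
1e-6). Default priors: Poisson mean 1 on the shift count per rate
vector, gamma(2, 5) on segment rates; both are arguments.

Chain lengths default to 2e4 iterations with 10% burn-in and 1000
saved samples; convergence is accepted at ESS > 200 (`ess()` uses
Geyer's initial positive sequence) and non-converged runs come back
flagged rather than silently accepted. These desk-scale defaults are a
deliberate choice: the package's acceptance surface is statistical
recovery on synthetic data of a few hundred lineages, for which these
lengths mix well, and every length is a config knob for larger data.

**Edge effects and the analysis window.** Seed lineages originate at
the simulation edge and extant lineages truncate at the young edge;
both create event pile-ups there. Real analyses buffer the interval of
interest with extra stages on both sides; the package does the same:
the generator's default simulation window (276–244.2 Ma) extends ~3 Myr
beyond the default analysis window (273.0–247.2 Ma), and rate
estimation is carried out on the inner window.

**Unsampled lineages.** Lineages that never fossilize are
preferentially short-lived, so rates estimated from sampled lineages
alone are biased low — at `q = 1`, `mu = 0.1` roughly 9% of lineages
are unsampled and the extinction rate loses ~15%. `augment_unsampled()`
performs model-based imputation: under exponential lifetimes the
expected number of missing lineages is `n p/(1-p)` with
`p = mu/(q+mu)`, their durations follow Exponential(`q+mu`), and the
extinction-rate estimate is iterated to self-consistency. Ghost
originations are spread over the observed origination quantiles. The
imputation is deterministic given its inputs and is used in the
package's recovery experiments; it assumes rates vary slowly relative
to the window, so treat it as a first-order correction, not a
replacement for a joint model.

## Diversity and traditional cross-checks

`ltt_diversity()` counts lineages whose `(Ts, Te]` interval covers
each grid age; on simulated histories it reproduces the truth exactly,
and the curve steps by exactly one at each event. `bin_counts()` +
`per_capita_rates()` give the boundary-crosser rates
(`p = -log(n_bt/(n_bt+n_ft))/dt` and the extinction analogue), with
bins undefined (missing, never zero) when no lineage crosses both
boundaries. Sampling completeness is the pooled three-timer ratio
`3T/(3T+PT)`; corrected richness divides sampled-in-bin counts by it.
`rate_correlation()` trims two bins from each series end before
correlating, because boundary-crosser rates are edge-biased. Sampled
diversity models, second-for-third and gap-filler rates, and quorum
subsampling are out of scope; the per-capita family is the retained
discrete-bin cross-check.

## Multivariate birth–death drivers

Predictors are LOWESS-smoothed where requested (the noisy isotope-type
series), min–max rescaled to [0, 1] so magnitudes cannot masquerade as
effect sizes, and linearly interpolated at 0.1 Myr
(`prepare_predictors()`). Constant series are flagged degenerate and
zeroed — a constant predictor is absorbed by the baseline and carries
no identifiable signal. The rate model is
`lambda(t) = lambda0 exp(sum_j G_j v_j(t))` (exponential link) or the
zero-clamped linear analogue; the likelihood reuses the exact
birth–death form with the lineage-time integral of the grid-linear
rate curve accumulated in closed form, so setting all `G = 0`
reproduces the constant-rate likelihood exactly.

Each `G_j` carries a horseshoe prior: `G_j ~ N(0, tau^2 kappa_j^2)`
with half-Cauchy local scales and a half-Cauchy global scale per rate
vector. The shrinkage weight reported per predictor is the posterior
mean of `1 - 1/(1 + tau^2 kappa_j^2)` — one minus the classical
shrinkage factor — with `w > 0.5` flagged as signal.

The sampler is Metropolis-within-Gibbs with three non-obvious design
choices, all forced by the non-conjugate likelihood:

- scales are updated by log-scale random-walk Metropolis on their
  half-Cauchy *marginals* rather than the usual inverse-gamma
  parameter expansion. The auxiliary-variable chain interleaves
  independence redraws of coupled heavy-tailed quantities; below
  `kappa ~ 1` it behaves as a near-driftless log-scale random walk and,
  in floating point, can spiral into an absorbing underflow state
  (`kappa = 0`, `nu = Inf`). The marginal random-walk kernel has
  exponential log-scale tails and no such trap.
- `G` steps are ridge-compensated: the predictors are non-negative, so
  raising `G_j` raises the mean rate that the baseline must offset;
  proposals shift `log lambda0` by `-dG * mean(v_j)` simultaneously,
  moving along the likelihood ridge.
- each predictor also gets a non-centered `(G, kappa)` scaling move
  and an independence redraw from the prior conditional; the latter
  accepts with probability one in likelihood-off runs, which makes the
  prior-sampling validation exact, and provides global escapes from
  the horseshoe's spike at zero.

The prior implementation is validated by a likelihood-off run whose
`G` samples are compared to direct horseshoe draws
(Kolmogorov–Smirnov), and the reversible-jump sampler by its Poisson
shift-count prior (chi-square): both checks are in the test suite.

Model choice between the links uses stepping-stone marginal
likelihoods (`mbd_marginal_loglik()`, ladder `beta_k = (k/K)^(1/0.3)`
with K = 8 by default) and `bayes_factor()`, reporting "no clear
support" when `|log BF| < 2`. Short windows (the stage-bounded
Asselian–Wordian-style intervals) are analysed by preparing the
predictors on that window. Predictors enter unlagged; no time-varying
`G` within a window.

## Spatial analyses

`hex_grid()` builds an icosahedral tessellation (subdivided icosahedron
projected to the sphere: `10 f^2 + 2` near-equal-area cells, twelve of
them pentagons); occurrences map to their nearest cell centre.
Assemblage dissimilarity is the corrected Forbes index,
`F' = a(n+sqrt(n)) / (a(n+sqrt(n)) + 1.5 b c)`, fixed to this form and
isolated in one function for substitution. `regionalize()` runs both
partitioning-around-medoids (k chosen by silhouette) and greedy
modularity on the shared-taxon graph, returning both labelings and
their adjusted-Rand agreement — it never auto-selects the final
regions, mirroring the practice of using the clusterings as a
reference for constructing spatial windows by hand.

`mst_standardize()` equalizes per-bin spatial footprints: while the
great-circle minimum-spanning-tree length over occupied cells exceeds
the threshold (the per-dataset median of raw per-bin lengths by
default), the cell with the fewest occurrences is removed. Among
equally data-poor cells the one whose deletion most shortens the tree
goes first, with the cell id as the deterministic final tie-break —
the removal order is otherwise unspecified in the field's
descriptions, and this choice also keeps the step lengths
non-increasing in practice, since data-poor cells sit at the tree's
periphery. The audit records raw and final lengths, per-step lengths
and removals per bin. Palaeorotation services are out of scope: the
generator carries palaeocoordinates directly, and externally rotated
coordinates can be supplied in the same columns.

## The synthetic-data generator

`simulate_bd()` is a Gillespie simulation of the piecewise-constant
birth–death process; `simulate_preservation()` thins lineage durations
with the stepwise preservation rate; `emit_occurrence_table()` censors
true ages to substage intervals, clusters occurrences into collections
(Poisson clustering within region-by-substage cells, one lithology and
coordinate pair per collection), and injects curation artefacts —
qualifiers, bracketed subgenera, terrestrial flags, out-of-range
occurrences — each recorded in a truth sidecar so curation
recall/precision are exactly computable. Default injection rates (5%
qualifiers, 5% subgenera, 5% terrestrial, 2% outliers, 50% carbonate,
4 regions, mean collection size 5) are round values chosen once to
resemble a moderately noisy PBDB export; the collection-size
distribution is exposed as a tunable because no canonical value
exists.

What the generator does not emulate: taxonomic synonymy and its
revision, spatial bias in sampling effort, lithology-linked
preservation heterogeneity, and real palaeorotation. Passing tests
therefore demonstrate correctness of the algorithms under the stated
models, not robustness to every bias of real data.

`simulate_predictors()` draws stationary Gaussian-process curves
(squared-exponential kernel, 0.5 Myr length-scale) rescaled to [0, 1].
The short length-scale is deliberate: smooth long-wavelength curves
live in a low-dimensional function space, and a handful of decoys can
then linearly reproduce a signal curve (R-squared above 0.9), making
driver recovery ill-posed no matter the sampler. Signal predictors
return the exact rate curves they generate through the exponential
link, so recovery experiments have pointwise ground truth.

## Experiment scale and numerical choices

Recovery experiments condition on dataset size (`simulate_bd_dataset`,
`simulate_mbd_dataset` redraw runs outside their size bands): the
constant-rate recovery runs at 120–400 lineages, the driver-recovery
design is near-critical (60 Myr window, 100 seed lineages, origination
baseline 0.05 against extinction 0.1) yielding 600–2000 lineages —
several hundred origination events, the information a shrinkage
analysis of ten correlated predictors needs. Two experiment-design
facts are worth knowing: trees grown from very few seed lineages and
conditioned on reaching a large size have systematically inflated
early growth (a survivorship effect), which a correct shift detector
reports as a real shift — constant-rate false-positive checks
therefore seed with 15 lineages; and the driver experiments' weight
threshold interacts with estimator attenuation, so posterior `G` must
stay near the generating value for `w > 0.5`, which sets the event
count above.

Numerical details: the closed-form lineage-time integral is exact (no
quadrature); MBD integration accumulates the trapezoid cumulative of
the grid-linear rate curve, exact for that curve class; truncated
exponential draws use `expm1`/`log1p` guards; degenerate inputs
(empty lineage sets, constant chains, single cells, zero-duration
bins) return defined values or named errors rather than crashing, and
the reversible-jump and horseshoe samplers reject (rather than
propagate) non-finite acceptance ratios that can only arise in
astronomically remote prior tails.
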