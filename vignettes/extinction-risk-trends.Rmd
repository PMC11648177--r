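---
title: "Assessing extinction-risk trends from abundance indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing extinction-risk trends from abundance indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(extrisk)
library(dplyr)
```

## The problem

Sharks and rays are slow-growing, late-maturing fishes whose populations
can be driven down by fisheries long before any stock assessment exists.
For most species the only quantitative evidence is a handful of
fishery-independent relative-abundance indices — research trawl survey
densities (kg per area swept) or standardized angling catch rates (fish
per angler-day) — each short, noisy, and covering only part of the
species' range. IUCN Red List Criterion A2 asks a precise question of
these data: what is the population reduction over the last three
generation lengths (3GL), and does it cross the 30% (Vulnerable), 50%
(Endangered) or 80% (Critically Endangered) threshold?

`extrisk` implements the full chain from index to category:

1. a Bayesian exponential state-space model that averages one or more
   indices into a posterior for the population trend (`fit_trend()`);
2. extrapolation of percent change over 3GL (`change_over_3gl()`), with
   generation length derived from longevity and maturity
   (`generation_length()`);
3. mapping of the decline posterior onto Criterion A2 category
   probabilities and a category call (`criterion_a2_probabilities()`,
   `assign_category()`);
4. the Red List Index (RLI) and national conservation responsibility
   (NCR) across an assessed fauna (`global_rli()`, `country_rli()`,
   `national_responsibility()`);
5. seeded simulators reproducing the generative structure the model
   assumes, so every stage is testable without confidential survey data
   (`sim_abundance_indices()` and friends).

## The trend model

Each index $i$ observes a single latent population trajectory. With
$\mu_t$ the log of expected abundance in year $t$:

$$\mu_{t+1} = \mu_t + r_t, \qquad r_t \sim N(\bar r, \sigma^2),$$

where $\bar r$ is the mean annual log rate of change and $\sigma^2$ the
process variance — year-to-year wobble in the realized rate. Observations
enter on the log scale through an index-specific constant catchability
offset and index-specific noise:

$$\log I_{i,t} = \log q_i + \mu_t + \varepsilon_{i,t}, \qquad
  \varepsilon_{i,t} \sim N(0, \tau_i^2).$$

The first index's $q$ is fixed at 1: only relative trend is identified,
and the fitted trajectory inherits the scale of the first index. Years
with no observation inside the span are latent states with no likelihood
term, so gaps need no imputation.

Priors are deliberately vague: $\bar r \sim N(0, 1000)$,
$\sigma^2 \sim \text{inverse-gamma}(0.001, 0.001)$ (approximately uniform
on the log scale), the same inverse-gamma on each $\tau_i^2$, a flat
normal on each free $\log q_i$, and a diffuse normal (sd 1000 on the log
scale) on the initial state centred at the log of the first observation.
The posterior is therefore data-dominated even for 20–30 point series.

Sampling is Gibbs/Metropolis via JAGS with the model specification built
by the package. The default schedule (`mcmc_settings()`) runs three
chains with distinct seeded RNG streams: 30,000 burn-in iterations, then
60,000 iterations thinned by 6 for 10,000 kept draws per chain — 30,000
posterior draws. Fits are bit-reproducible given the seed. Every fit is
screened with the Geweke stationarity diagnostic (early 10% vs late 50%
of each chain, spectral-density-at-zero variance estimates, threshold
p = 0.05) on $\bar r$ and $\sigma^2$; a failing fit is returned flagged
with a warning rather than discarded, since at short test schedules
occasional marginal failures are expected and the flag is what the
pipeline records.

Interval summaries use the highest posterior density (HPD) interval: the
shortest window over the sorted draws spanning
$\lceil 0.95 n \rceil$ inter-draw steps. For skewed decline posteriors
the HPD is noticeably shorter than the equal-tailed interval.

Posterior predictive checks (`posterior_predictive_check()`) draw
replicated observations per posterior draw and flag data points outside
the central 95% of their predictive distribution; the fit passes overall
when the credible band of the trajectory sits inside the predictive band
at every observed point.

## From trend to category

Generation length uses the longevity–maturity shortcut
$GL = A_{max} + (A_{max} - A_{mat})\,z$ with $z = 0.5$ by default —
larger than the mammalian convention of 0.3 to allow for age structures
truncated by exploitation and for systematic underageing in
elasmobranchs. The Criterion A2 window is $3\,GL$ years ending at the
last fitted year.

When $3\,GL$ fits inside the observed span, percent change is read off
the latent trajectory per draw,
$100(e^{\mu_{end}-\mu_{start}} - 1)$, interpolating log-linearly when
the window start falls between years. When $3\,GL$ exceeds the span —
the usual case for long-lived species — each draw's own $\bar r$ is
extrapolated deterministically: $100(e^{\bar r \cdot 3GL} - 1)$. A
stochastic alternative would re-draw annual rates $r_t$ for the
unobserved years, widening the interval; we use the deterministic form,
which reports the smooth projected trend and keeps the extrapolated
quantity a function of sampled parameters only.

The decline posterior $D = -\text{change}$ is partitioned at the A2
thresholds: $P(CR) = P(D \ge 80)$, $P(EN) = P(50 \le D < 80)$,
$P(VU) = P(30 \le D < 50)$, remainder `LC_or_NT`. These empirical
fractions always sum to one. The assigned category is the most probable
one, ties resolved toward the more threatened side (precautionary, and
consistent with how assessors treat borderline evidence). When
`LC_or_NT` dominates, the NT/LC split is made on the median decline:
NT from 20% decline upward (the default `nt_band` lower edge), LC
below. We deliberately do not return LC when the median passes 30%
while the probability mass still favours `LC_or_NT`: category calls
must be monotone — pushing the whole posterior further down can never
produce a *less* threatened category — and an upper cutoff would break
that at the band edge. The band is configurable; the NT concept
("approaches but does not meet a threshold") has no unique quantitative
form, and expert judgment in real assessments is accommodated through
explicit overrides (`assess_decline(..., override = )`), which are
recorded next to the modeled category, never in place of it.

## Red List Index and national responsibility

Categories are weighted LC = 0, NT = 1, VU = 2, EN = 3, CR = 4, with
extinction weight $W_{EX} = 5$; Data Deficient species are excluded
entirely. The equal-weight index over $N$ assessed species is
$RLI = 1 - \sum_s W_s / (W_{EX} N)$: 1 when every species is LC, 0 when
all are extinct, and each one-step uplisting of a single species moves
it by exactly $1/(W_{EX} N)$. Country disaggregation weights each
species by $p_{su}$, the proportion of its global range inside country
$u$'s EEZ:

$$RLI(t, u) = 1 - \frac{\sum_s W_{(t,s)}\, p_{su}}
  {W_{EX} \sum_s p_{su}},$$

and national conservation responsibility is the raw range-weighted
threat sum $\sum_s W_{(t,s)}\, p_{su}$, normalized so the top country
scores 1. A country whose endemics are all LC scores 0 regardless of
how much range it holds. Backcast (retrospectively corrected)
categories, not originally published ones, feed the index, so that its
decline reflects genuine status change rather than knowledge change.

The packaged table (`extrisk_example("swio_endemics.csv")`) carries the
published assessment of the 70 endemic sharks and rays of the southwest
Indian Ocean region across epochs 1980, 2005 and 2020:

```{r rli}
tbl <- read_species_table(extrisk_example("swio_endemics.csv"))
rli_series(tbl, c(1980, 2005, 2020)) |>
  mutate(rli = round(rli, 3))
```

Per-species threat-code attribution in this fixture is exact only for
species named in the source text; the remainder is reconstructed to
match the published aggregate counts (see `?extrisk_example`).

## What the simulators emulate — and what they do not

`sim_abundance_indices()` is the forward model of the fit: exponential
trend, process variability, log-normal observation noise, per-index
catchability. Defaults mirror the survey layout behind the packaged
assessment — 27 annual observations starting 1991 (the trawl span) —
with log-scale observation sd 0.3, a realistic figure for standardized
survey CPUE; the real surveys publish no noise magnitude, so this is a
package default, not a reported value. `sim_species_table()` draws
categories per epoch independently from stated frequencies (no
cross-epoch trajectory coherence), and `sim_range_matrix()` draws range
rows from a symmetric Dirichlet, the simplest distribution honouring
the endemic sum-to-one constraint.

Passing tests on these simulators demonstrates that the pipeline
recovers what it assumes: correct inference under the model, correct
arithmetic, correct identities. It does not demonstrate robustness to
what real survey indices contain — catchability drift, range shifts
moving animals out of the surveyed footprint (the reason one species in
the source assessment was overridden from EN-consistent model output to
VU), zero-inflated hauls, or standardization artifacts. Those need the
delta-GLMM standardization stage, which is upstream of and out of scope
for this package: `extrisk` consumes already-standardized indices.

## Numerical choices and problem sizes

* Reporting rounds half-up: percentages to 1 decimal, RLI and NCR to 3
  decimals, matching assessment-report conventions; computations are
  exact internally.
* The Geweke estimator fits an AIC-selected Yule-Walker AR model for
  the spectral density at zero; degenerate (zero-variance) chains are
  an error, as is any chain under 100 draws.
* HPD ties (flat stretches) resolve to the first narrowest window over
  the sorted draws; all-equal draws give a zero-width interval.
* Criterion A2 probability ties resolve toward the more threatened
  category.
* Dividing by a zero maximum in NCR normalization is refused: raw zero
  scores are returned with a warning instead.
* The test suite and examples run the sampler at reduced schedules
  (single chain, a few thousand kept draws) against series of 10–27
  years; posterior medians there are stable to about $10^{-3}$, ample
  for the properties tested. Production fits should use the default
  `mcmc_settings()` schedule. Calibration properties (HPD coverage of
  the true rate across 50 simulated surveys, Geweke null calibration
  across 100 chains) are exercised at exactly those replicate counts in
  the tests.

## Known limitations

* One latent trajectory per fit: indices covering different population
  components are averaged, not modelled hierarchically.
* No density dependence or carrying capacity — the exponential model is
  the Criterion A convention, not a population dynamics claim.
* Backward extrapolation assumes the recent mean rate held throughout
  3GL; historically steeper or shallower declines are invisible to it.
* Criteria B–E (range geometry, small-population rules) are not
  computed; categories arriving from those routes are carried as data.
* Range proportions are consumed as numbers; no GIS is performed.
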