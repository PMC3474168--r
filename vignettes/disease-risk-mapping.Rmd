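---
title: "Small-area disease risk mapping and two-wave change detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area disease risk mapping and two-wave change detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`arealrisk` implements a repeated geo-mapping analysis of small-area disease
risk: indirect sex-standardization, Besag–York–Mollié (BYM) smoothing of
area-level relative risks by MCMC, posterior-certainty classification and
ranking, and detection of evidential positional changes between two survey
waves. This vignette records the model, its assumptions, the tunable
parameters, the synthetic-data generator the package is validated on, and
the numerical and design choices a maintainer should know about.

## The estimation problem

The unit of analysis is an areal unit ("parish") with, per survey wave and
sex, a count of examined children and a count with the binary outcome
(any caries experience, dmfs > 0). Two quantities per area are wanted: a
stable estimate of its relative risk against the whole-population level,
and a statement of how certain the data make an elevated or lowered risk.
Small denominators (one to a few hundred children) make the raw
observed-to-expected ratio too noisy for either purpose; the hierarchical
model supplies the stability, and the posterior supplies the certainty.

## Standardization

Reference rates are the sex-specific outcome rates of the *total* study
population of the wave; expected counts apply those rates to each area's
sex-specific denominators (`expected_counts()`). Two consequences are used
as exact invariants in the tests: with internally computed rates,
`sum(E) == sum(O)` to floating tolerance, and the E-weighted mean of the raw
relative risks is 1. Standardization is by sex only — an age column is
accepted but ignored, because the emulated study design has essentially
stable age structure between waves. Each wave is standardized independently;
no reference population is shared across waves, so a secular change in
overall prevalence does not masquerade as an area-level risk change.

Areas with zero examined children are kept with `E = 0` (maps must stay
complete); they contribute no likelihood to the model and their raw RR is
flagged undefined rather than invented.

## The BYM model and its sampler

For area $a$: $O_a \sim \mathrm{Poisson}(E_a\theta_a)$,
$\log\theta_a = \alpha + u_a + v_a$, with the intrinsic CAR prior on $u$
(precision $\tau_u$, sum-to-zero per connected component of the adjacency
graph), exchangeable $v_a \sim N(0, 1/\tau_v)$, $\alpha \sim N(0, 10^2)$,
and $\mathrm{Gamma}(0.5, 0.0005)$ hyperpriors on both precisions — the
long-standing WinBUGS disease-mapping convention; all are arguments of
`fit_bym()`. A Poisson likelihood is used even though the generator is
binomial at child level: at 12–16% prevalence the approximation is good,
it matches how observed/expected disease-mapping toolchains work, and the
deliberate generator/fitter mismatch doubles as a robustness check.

Sampling is Metropolis-within-Gibbs:

* random-walk Metropolis for $\alpha$, each $u_a$ and each $v_a$. The
  $u$-updates are executed jointly over *color classes* of the graph
  (greedy coloring): areas in one class share no edge, so their full
  conditionals are independent and a vectorized joint accept/reject step is
  exactly equivalent to single-site updating. The $v$-updates are
  conditionally independent everywhere and vectorized directly. This keeps
  the sampler in plain R at roughly one second per chain for 66 areas and
  15,000 sweeps, which is why no compiled code is used.
* conjugate Gibbs draws for the precisions:
  $\tau_u \sim \mathrm{Gamma}(a + (N - C)/2,\; b + \tfrac12\sum_{a\sim b}(u_a-u_b)^2)$
  with $N$ areas and $C$ graph components (the ICAR rank deficiency), and
  $\tau_v \sim \mathrm{Gamma}(a + N/2,\; b + \tfrac12\sum_a v_a^2)$.
* proposal scales adapt towards 30–50% acceptance in batches of 50 sweeps
  during burn-in only, and are frozen afterwards so detailed balance holds
  over the kept draws.
* after every sweep $u$ is re-centered per component; when the graph is
  connected the removed level is added to $\alpha$, leaving every
  $\theta_a$ unchanged while keeping the parametrization identified.

Isolated areas (no neighbors) keep $u_a = 0$: the ICAR prior carries no
information for them, so all their heterogeneity is absorbed by $v_a$.

Defaults are 2 chains, 5,000 burn-in, 10,000 kept draws, thin 1. Summaries
are the posterior median of $\theta_a$ as the smoothed relative risk (the
posterior mean is exposed alongside, since either convention appears in
practice; the median is the default for robustness to the right skew of
small-count posteriors), the strict exceedance fraction
$\Pr(\theta_a > 1 \mid \text{data})$, and 95% equal-tailed credible
intervals. Convergence reporting is split-chain $\hat R$ on
$\log\theta_a$ and an autocorrelation-based effective sample size
(Geyer-style truncation at the first negative pair sum).

### Validation against a closed form

With a single isolated area, the unstructured term disabled
(`fix_tau_v = 1e8`) and a wide intercept prior, the model degenerates to
$O \sim \mathrm{Poisson}(E\theta)$ with an almost-flat prior on
$\log\theta$, whose posterior is $\mathrm{Gamma}(O, E)$ — the $a,b \to 0$
limit of `conjugate_posterior_single_area()`. The tests and the acceptance
script compare the sampler's posterior mean (within 3 Monte-Carlo standard
errors), quantiles, and exceedance probability (within 0.03 of
incomplete-gamma quadrature) against this closed form. `fix_tau_u` /
`fix_tau_v` exist in the public interface precisely to make this
degenerate-case validation expressible.

## Certainty classification, ranks, and change detection

The classification is a pure function of the exceedance probability: red if
$\Pr(RR>1\mid\text{data}) > 0.95$, green if the complement exceeds 0.95,
yellow otherwise. The inequalities are strict, so a probability exactly at
the threshold is yellow; a $10^{-9}$ guard absorbs floating-point
representation noise (e.g. `1 - 0.95 > 0.05` in doubles) without changing
the strict-inequality semantics. Certainty ranks order areas by exceedance
probability (1 = most certainly lowered, N = most certainly elevated), with
deterministic tie-breaks by SmRR then area id — ties are practically absent
with continuous posteriors, but determinism keeps outputs diff-stable.

Between two waves, an area shows an *evidential positional change* when its
color changed **and** its exceedance probability moved by at least
`delta = 0.25`. The 25% is read as an absolute difference in probability
(25 percentage points), not a relative change: the quantity is itself a
probability, and a relative reading would make near-zero probabilities
hypersensitive. The boundary shift of exactly 0.25 counts ("at least").
Each wave is smoothed independently before comparison; there is no
borrowing of strength across waves, so the change report compares two
genuinely separate posteriors.

## The synthetic-data generator

The generator (`sim_config()`, `simulate_two_waves()`) emulates the study
conditions the pipeline is meant for:

* **Geography** — a 6×11 unit-square lattice with rook adjacency stands in
  for a 66-parish region. Queen contiguity is available for polygon input
  (corner contact counts), computed from shared vertices as spatial-weights
  libraries do; rook demands a shared edge.
* **Population** — each (area, sex) denominator is
  `max(1, round(Lognormal(log(mean/2), dispersion)))` with defaults
  `mean_children_per_area = 151` and `dispersion = 0.35`, giving
  ~10,000–10,600 children per wave across 66 areas, matching the emulated
  survey totals. Dispersion 0 gives identical areas (used as a degenerate
  test limit).
* **Outcome** — per-child Bernoulli, aggregated as
  `Binomial(n, rate_sex * exp(log_rr_area))` truncated at 1. Baseline rates
  default to 0.16 in wave 1 and 0.114 in wave 2 (the caries-free share
  improving 84.0% → 88.6%), identical for boys and girls since no sex split
  is published; both are configurable.
* **Risk surface** — `log_rr = u + v`, with `u` a proper-CAR draw
  (autocorrelation 0.99) centered per component and rescaled to marginal
  s.d. `sigma_u` (the intrinsic prior itself is improper, so the
  near-intrinsic proper surrogate is the standard simulation workaround),
  and `v` iid normal with s.d. `sigma_v`; the sum is re-centered so it is a
  pure contrast. Defaults `sigma_u = sigma_v = 0.3` were calibrated so the
  *smoothed* polarization ratio of a default wave falls in the published
  4.0–7.2 range (measured median ≈ 5.7 for wave 1 at these settings).
* **Two waves** — wave 2 reuses wave 1's surface, multiplies the risk of
  each area in `changed_areas`, re-centers, re-draws populations from a
  distinct sub-stream, and applies the wave-2 baseline. All randomness
  flows from one master seed through named sub-streams
  (`substream_seed()`), so stages are independently reproducible and the
  composed pipeline is bit-identical to its manual stage-by-stage
  equivalent.

What the generator deliberately does **not** model: child-level covariates,
recall-interval-driven non-participation (coverage is ~77% in the emulated
design), within-area clustering beyond the area effect, and between-wave
correlation of area population sizes. Passing tests therefore demonstrate
the statistical machinery under idealized sampling, not robustness to
informative missingness or covariate confounding.

## Replication sizes and what the checks show

The test-suite and acceptance-script replications use shortened chains
(1 chain, 600 burn-in, 1,500 kept draws) for replicate-heavy checks; at
1,500 draws an exceedance probability carries ~0.013 Monte-Carlo standard
error, which is adequate for banded assertions, and the single-area oracle
comparison uses 2 × 6,000 draws. Replicate counts are 30–50 for null
calibration, 10–20 for recovery and change detection.

* **Null calibration** — on flat-risk data (true RR = 1 everywhere, ~150
  children per area) the fraction of red flags stays far below 10%: the
  hierarchical smoothing is conservative, favoring specificity.
* **Shrinkage** — on every synthetic fit, the variance of log SmRR across
  areas with cases is below the variance of the log raw ratios.
* **Recovery** — with an unstructured surface of s.d. 0.4 and ~300 children
  per area, the correlation between true and smoothed log risks averages
  well above 0.7.
* **Change detection** — planted 2.5-fold two-wave changes are recovered at
  roughly half sensitivity (areas already confidently red/green before the
  change cannot change color, by construction of the rule). Under the
  calibrated surface spread, sampling noise alone also produces evidential
  flags in roughly 5–6 of 66 stable areas per replicate pair: the
  conjunction rule filters modest flips but cannot distinguish a genuine
  moderate change from an unlucky pair of draws at this information level.
  Users comparing real waves should read small evidential sets with that
  base rate in mind — a point worth remembering given that published
  analyses of this design report evidential counts of the same order.

## Known limitations

* The Poisson likelihood slightly overstates variance relative to the
  binomial truth at 16% prevalence; the effect is conservative.
* Exceedance probabilities from 1,500-draw runs are granular at 1/1500;
  production runs should use the defaults (2 × 10,000).
* The ICAR surrogate in the *generator* (proper CAR at 0.99) has slightly
  less long-range correlation than a true intrinsic field.
* No spatio-temporal joint model: waves are smoothed independently by
  design, which matches per-year surveillance practice but forgoes power
  that a joint model would add.
* GeoJSON/GAL support covers the formats' common dialects, not every
  corner of the specifications; shapefiles and CRS handling are out of
  scope.
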