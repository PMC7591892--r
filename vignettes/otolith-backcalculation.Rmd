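---
title: "Back-calculating fish size-at-age from otoliths: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Back-calculating fish size-at-age from otoliths: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otogrow)
```

## The problem

Sagittal otoliths accrete annual calcium-carbonate increments, so the
radius of an otolith section at ring *i* records how large the otolith —
and, through a proportionality relationship, the fish — was at age *i*.
Back-calculation turns a single lethal sample into a full size-at-age
trajectory per fish, which is what growth models actually need. otogrow
implements this chain end to end: a Bayesian fit of the length–radius
relationship (with imputation of unmeasured hatch radii), the Modified Fry
back-calculation with full uncertainty propagation, and hierarchical
Bayesian Von Bertalanffy growth curves on the resulting trajectories.

## The proportionality model

The anchor of the whole method is the biological intercept: at hatching, a
fish of the species has total length $L_{0p}$ (a species constant, mm) and
otolith radius $R_{0p}$ (measured per fish where the nucleus was legible).
Between hatching and capture, length and otolith radius are linked by a
power law:

$$L_{cpt} = L_{0p} - b\,R_{0p}^{c} + b\,R_{cpt}^{c}$$

where $L_{cpt}$ and $R_{cpt}$ are length and radius at capture. The
regression parameters get informative priors $b \sim \mathrm{N}(200, 200)$
and $c \sim \mathrm{N}(1, 1)$, both truncated at zero: positivity of $b$ is
not cosmetic, it is what guarantees the intercept $a = L_{0p} - b R_{0p}^c$
stays below $L_{0p}$ so the log-domain of the back-calculation formula is
well defined. The likelihood is a normal observation model on $L_{cpt}$
with an estimated residual scale $\sigma \sim \mathrm{halfN}(0, 50)$ mm —
the simplest error structure consistent with a single observed regression.

**Missing hatch radii.** For many otoliths the nucleus cannot be measured.
Rather than dropping those fish, each missing $R_{0p}$ enters the model as
a parameter: known and missing hatch radii are modelled as draws from a
common truncated-normal population whose mean and spread are estimated
jointly (hyperpriors centred on the mean of the known values, scales
0.1 mm — weakly informative at the 0.008–0.136 mm scale of reef-fish
nuclei). Each missing radius therefore acquires its own posterior, updated
by the fish's capture length through the regression. A group needs at
least two known hatch radii; with one, the radius population is
unidentifiable, and such groups are skipped entirely.

## Back-calculation with uncertainty

For every retained posterior draw $(b, c, R_{0p})$ we form the
per-individual intercept

$$a[i] = L_{0p} - b\,R_{0p}[i]^{c}$$

and evaluate the Modified Fry interpolation at every measured increment
radius $R_i$:

$$L_i = a + \exp\!\left(\ln(L_{0p}-a) +
  \frac{[\ln(L_{cpt}-a) - \ln(L_{0p}-a)]\,[\ln R_i - \ln R_{0p}]}
       {\ln R_{cpt} - \ln R_{0p}}\right)$$

This is log-linear interpolation of intercept-shifted length against log
radius, pinned at both ends: $L_i = L_{0p}$ exactly at $R_i = R_{0p}$ and
$L_i = L_{cpt}$ exactly at $R_i = R_{cpt}$, for every draw — which is why
the reported standard deviation is zero at the two anchors and strictly
positive in between. Summaries over the draws (default 4,000: 4 chains ×
2,000 iterations, 1,000 warmup) give the published-style per-age mean and
sd columns (`Li_sp_m`/`Li_sp_sd` by species, `Li_sploc_m`/`Li_sploc_sd` by
species and location).

Occasionally a draw violates the log-domain ($L_{cpt} \le a$, possible for
extreme $b$ draws on small fish). Such draws are skipped for that
individual and counted; estimates resting on fewer than half the draws are
flagged `unreliable` rather than silently reported.

**Eligibility.** Back-calculation is not attempted for fish captured at
age one (their single increment carries no trajectory information) and —
a choice forced by the interpolation itself, which needs two distinct
anchors — age zero.

## Growth curves

Size-at-age follows the Von Bertalanffy function
$L_t = L_\infty(1 - e^{-K(t - t_0)})$. Back-calculated points within a
fish are strongly auto-correlated, so pooling them naively would
overstate the information content. The hierarchical model therefore fits
one curve per fish, $L_{\infty j}$ normal and $\log K_j$ normal around
population means, with the population curve as the object of inference.
$t_0$ is shared at the population level by default: with a handful of
points per fish, individual $t_0$ is weakly identified (a per-individual
switch exists for data-rich groups). The per-point back-calculation sd can
enter the likelihood as known additive measurement variance (on by
default), honouring the uncertainty the back-calculation propagated.

Priors for $L_\infty$ and $K$ are supplied per group — in practice from a
life-history database such as FishBase — through `vb_priors()`; nothing is
fetched from a live service, keeping runs reproducible and offline.
Hierarchical fits require at least five individuals with age at capture
above two years; age-0 hatch-length points are retained in the fitted
data, anchoring the curve near the origin.

The comparison model is a plain (non-hierarchical) Bayesian fit to one
(age, length) point per fish, eligible only for groups of more than ten
individuals. Comparing the two population curves on an age grid reports
95% credible bands, their per-age overlap, and whether the back-calculated
median curve lies below the raw one. Because back-calculated data include
the hatch lengths, their fits typically pull $K$ up and $L_\infty$ down
relative to capture-only fits — the direction the package's validation
study checks. In simulation the $L_\infty$ effect is the robust one; the
$K$ shift is small and can change sign between replicate batches, because
the raw fit's informative prior and free $t_0$ already absorb much of the
missing-origin information that drives the effect in real collections.

**Convergence protocol.** Fits run at 2,000 iterations (1,000 warmup). If
any monitored R-hat exceeds 1.01, the fit is repeated at 4,000/2,000; if
that still fails, the individuals whose parameters carry the worst R-hat
are removed one at a time (at most three) with every action logged — an
automated stand-in for inspecting MCMC chain plots by eye. R-hat is
compared against 1.01 rather than 1.0 because the statistic is bounded
below by one; a threshold of exactly 1.0 would retrigger forever (the
protocol tests exploit precisely this to exercise the escalation path).

## MCMC engine

All models are sampled with JAGS (via rjags), which expresses the two
model families directly — including missing hatch radii as stochastic
nodes and the truncated priors. Two consequences of using a
Gibbs/slice-based sampler are documented choices rather than omissions:
the hierarchical model uses the centered parameterization (non-centered
variants remedy a Hamiltonian-sampler pathology that does not arise
here), and posterior diagnostics are R-hat and effective sample size
(divergence counts are a Hamiltonian-specific concept). Chains are seeded
individually, so every fit is reproducible from one integer seed.

## The synthetic-data generator

`simulate_dataset()` emulates exactly the statistical structure the
analysis assumes, with truth retained for recovery tests:

* per-species power-law length–radius coupling, generated by inverting
  the proportionality relationship at the individual's hatch radius, so
  the back-calculation model is well specified and parameter recovery is
  a well-posed test (an optional multiplicative radius-noise switch
  supports robustness studies);
* individual growth heterogeneity: $L_{\infty j}$ normal (truncated above
  the hatch length), $K_j$ lognormal, around population values — both
  kept positive by construction;
* $t_0$ derived per individual from the hatch anchor,
  $t_{0j} = \ln(1 - L_{0p}/L_{\infty j}) / K_j$, so every true curve
  passes through the hatch length at age zero (a configured population
  $t_0$ would be redundant given this constraint, so none exists);
* integer ages at capture, uniform on [2, `max_age`], matching annual
  increment reads;
* Gaussian observation noise on capture length only (the one observed
  regression response), floored above the hatch length;
* hatch radii masked completely at random, never below two known per
  group.

Defaults (`b = 200`, `c = 1`, `L0p = 2.5` mm, hatch radii
0.05 ± 0.02 mm, $L_\infty$ = 400 mm, K = 0.4/yr, σ = 5 mm, 30% masking)
sit inside the ranges reported for Pacific reef-fish otolith collections.
What the generator does *not* emulate — growth–otolith decoupling ("growth
effects"), reader error in ring counts, seasonal checks, non-random
missingness — bounds what passing tests show: they validate the
implementation under its own assumptions, not the biology of any real
collection.

## Validation studies and problem sizes

The packaged studies (also run by `scripts/acceptance.R`) use desk-scale
problem sizes chosen to make Monte Carlo error small relative to the
tolerances: 10,000 random input sets for the interpolation identities;
20 simulation seeds × 40 fish (30% masked, 4 chains × 500 retained draws)
for proportionality recovery, judged by mean absolute relative error of
the posterior means and pooled 95% CI coverage of the masked radii;
20 fish for hierarchical recovery; and 20 seeds of the full
back-calculation → growth-fit → comparison chain for the
direction-of-bias and band-overlap study. Representative results: anchor
identity error at machine precision, oracle closure below $10^{-12}$ mm,
recovery errors of 1–3% against thresholds of 5–10%, masked-radius
coverage near 98%, and band overlap in 20/20 seeds.

## Numerical choices and limitations

* Anchor identities are enforced exactly (the interpolation special-cases
  $R_i \in \{R_{0p}, R_{cpt}\}$), so floating-point drift cannot leak
  into the zero-sd guarantee at the endpoints.
* Truncated-normal simulation draws use bounded rejection sampling, which
  is exact and fast at these scales.
* Slow mixing, not wrongness, is the failure mode of the Gibbs sampler on
  the correlated $(b, c)$ and $(L_\infty, K)$ pairs; the convergence
  protocol (retry, then targeted removal) and per-fit seeds make this
  visible and reproducible. Multi-seed studies run with
  `on_nonconvergence = "warn"` so one slow replicate cannot abort a
  batch; single-group analyses default to erroring.
* The two-reader ageing CV uses the sample standard deviation
  (divisor R − 1), the standard ageing-precision convention; flagging is
  strict at the 5% threshold.
* Group eligibility counts known hatch radii among age-eligible members
  (the fish that actually enter the fit), and location-stratified groups
  are never larger than their species group.
* The pipeline (`run_pipeline()`) is the orchestration entry point;
  a stage failure in one group halts only that group's downstream
  stages, and the JSON manifest (stages, exclusion ledger accounting for
  every individual, diagnostics, seed) is written even on partial
  failure.
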