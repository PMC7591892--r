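# otogrow

Back-calculated size-at-age for fishes from otolith increments, with
Bayesian uncertainty propagation and hierarchical Von Bertalanffy growth
modelling.

Sagittal otoliths accrete annual increments, so measured ring radii record
an individual's growth history. otogrow estimates body length at each past
age from those radii, for multi-species collections where hatch radii are
sometimes unmeasurable, and fits growth curves to the reconstructed
trajectories. It is aimed at fisheries and reef-fish ecologists working
with long-format otolith increment datasets (one row per fish × age).

## The models

**Length–radius proportionality** (fitted per species, or per species ×
location, with JAGS):

```
L_cpt = L_0p − b·R_0p^c + b·R_cpt^c,   L_cpt ~ Normal(·, σ)
b ~ N(200, 200) T(0,∞),  c ~ N(1, 1) T(0,∞)
```

with `L_0p` the species length at hatching and `R_0p` the per-fish otolith
radius at hatching. Missing `R_0p` values are treated as parameters drawn
from the same truncated-normal population as the known ones, so each gets
its own posterior.

**Modified Fry back-calculation**, evaluated for every posterior draw with
the per-fish intercept `a = L_0p − b·R_0p^c`:

```
L_i = a + exp( ln(L_0p − a) + [ln(L_cpt − a) − ln(L_0p − a)] ·
               [ln R_i − ln R_0p] / [ln R_cpt − ln R_0p] )
```

Means and standard deviations over the 4,000 retained draws give per-age
length estimates with propagated uncertainty (zero at the hatch and
capture anchors, positive in between).

**Growth**: a hierarchical Bayesian Von Bertalanffy model
`L_t = L∞(1 − e^(−K(t − t0)))` with individual-level `(L∞_j, K_j)` around
population means (accounting for the strong within-fish auto-correlation
of back-calculated points), plus a plain Bayesian fit on size-at-capture
for comparison via 95% credible-band overlap.

Eligibility rules: ≥ 2 known hatch radii per group; capture ages 0 and 1
excluded from back-calculation; hierarchical fits need ≥ 5 individuals
with capture age > 2; raw fits need > 10 individuals; otoliths whose
two-reader ageing CV exceeds 5% are flagged for a common re-read.

## Worked example

```r
library(otogrow)

cfg <- simulation_config(n_species = 1, n_individuals_per_species = 15, seed = 1)
sim <- simulate_dataset(cfg)           # synthetic data with retained truth
sim$dataset
#> <growth_dataset> 15 individuals, 95 increment reads, 1 species

res <- run_backcalculation(sim$dataset, "species",
  settings = mcmc_settings(chains = 2, iter = 1500, warmup = 750, seed = 1,
                           on_nonconvergence = "warn"))
res$posteriors[[1]]
#> <proportionality_posterior> group Simulus|synthetica_1: 3000 draws, 5 imputed hatch radii
#>   b = 200.81, c = 0.996, sigma = 6.21 (posterior means)
```

The generative truth here was b = 200, c = 1, σ = 5: the fit recovers the
regression and imputes the five masked hatch radii. The annotated
increment table now carries per-age length estimates with uncertainty:

```r
head(res$dataset$increments[c("individual_id", "age_i", "li_sp_m", "li_sp_sd")])
#>   individual_id age_i li_sp_m li_sp_sd
#> 1 sim_01_001        0     2.5     0        # hatch anchor: exact
#> 2 sim_01_001        1   133.      3.93     # interior: propagated sd
#> 3 sim_01_001        2   220.      2.15
#> 4 sim_01_001        3   277.      0        # capture anchor: exact
```

Growth curves on the back-calculated trajectories versus raw
size-at-capture:

```r
est <- res$estimates[res$estimates$grouping == "species", ]
fd  <- filter_for_hierarchical_fit(est, sim$dataset$individuals)
post <- fit_vb_hierarchical(fd, vb_priors(linf_mean = 400, linf_sd = 100, k_mean = 0.4),
                            mcmc_settings(chains = 2, iter = 1500, warmup = 750, seed = 2))
post
#> <vb_posterior> hierarchical fit, 1500 draws, 14 individuals, 88 observations
#>   Linf = 393.7 mm, K = 0.411 /yr, t0 = -0.015 yr (posterior means)

raw <- fit_vb_raw(sim$dataset$individuals,
                  vb_priors(linf_mean = 400, linf_sd = 100, k_mean = 0.4),
                  mcmc_settings(chains = 2, iter = 1500, warmup = 750, seed = 3))
cmp <- compare_growth_curves(post, raw, 0:8)
attr(cmp, "global_overlap")
#> [1] TRUE
```

Truth was L∞ = 400 mm, K = 0.4/yr. The hierarchical fit (which sees the
age-0 hatch lengths) lands on L∞ = 393.7, K = 0.411; the raw fit's bands
overlap it at every age — the standard validation that back-calculation
did not distort the growth signal. `run_pipeline(pipeline_config(...))`
chains all of these stages (validate → QC → back-calculate → growth →
compare) under one seed and writes a JSON run manifest.

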