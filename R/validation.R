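#' Modified Fry identity and monotonicity study
#'
#' Draws random valid back-calculation inputs across the realistic range of
#' reef-fish otolith data and measures how exactly the Modified Fry
#' interpolation honours its two anchor identities (hatch and capture), and
#' whether back-calculated length increases strictly with increment radius
#' for growing fish.
#'
#' @param n Number of random input sets.
#' @param seed RNG seed.
#' @param n_monotone Subset of inputs probed on a radius grid for
#'   monotonicity.
#' @return List: `max_rel_err_hatch`, `max_rel_err_capture` (worst relative
#'   anchor errors), `monotone_frac` (fraction of probed curves strictly
#'   increasing), `n`.
#' @export
mf_identity_study <- function(n = 10000, seed = 1, n_monotone = 300) {
  set.seed(seed)
  l0p <- runif(n, 1.5, 4.5)
  lcpt <- runif(n, 30, 900)
  r0p <- runif(n, 0.008, 0.14)
  rcpt <- runif(n, 0.2, 3.9)
  b <- runif(n, 10, 400)
  cc <- runif(n, 0.5, 2)
  a <- biological_intercept_a(l0p, r0p, b, cc)
  err_h <- abs(modified_fry(lcpt, l0p, rcpt, r0p, r0p, a) - l0p) / l0p
  err_c <- abs(modified_fry(lcpt, l0p, rcpt, r0p, rcpt, a) - lcpt) / lcpt
  idx <- sample(which(lcpt > l0p & rcpt > r0p), n_monotone)
  mono <- vapply(idx, function(i) {
    ri <- seq(r0p[i], rcpt[i], length.out = 40)
    all(diff(modified_fry(lcpt[i], l0p[i], rcpt[i], r0p[i], ri, a[i])) > 0)
  }, logical(1))
  list(max_rel_err_hatch = max(err_h), max_rel_err_capture = max(err_c),
       monotone_frac = mean(mono), n = n)
}

#' Noise-free oracle closure study
#'
#' Simulates a dataset with zero observation noise, replaces the posterior
#' by a point mass at the generative parameters (and true hatch radii for
#' masked fish), and measures the worst absolute difference between
#' back-calculated and true lengths over every fish and age. Under the
#' body-proportional generative model this must vanish to numerical
#' precision.
#'
#' @param seed RNG seed for the simulated dataset.
#' @param n_individuals Fish in the simulated group.
#' @return List: `max_abs_err_mm`, `n_estimates`.
#' @export
oracle_closure_study <- function(seed = 1, n_individuals = 25) {
  cfg <- simulation_config(n_species = 1,
                           n_individuals_per_species = n_individuals,
                           sigma_length = 0, missing_r0p_rate = 0.3,
                           true_b = 180, true_c = 1.1, seed = seed)
  sim <- simulate_dataset(cfg)
  truth <- sim$truth$individuals
  post <- point_mass_posterior(
    sim$dataset$individuals, b = 180, c = 1.1,
    r0p_values = setNames(truth$r0p_true, truth$individual_id))
  est <- backcalculate_group(sim$dataset$individuals,
                             sim$dataset$increments, post)
  j <- dplyr::inner_join(est, sim$truth$lengths,
                         by = c("individual_id", "age_i"))
  j <- j[!is.na(j$length_mean), ]
  list(max_abs_err_mm = max(abs(j$length_mean - j$true_length)),
       n_estimates = nrow(j))
}

#' Length-radius parameter recovery study
#'
#' Repeated-simulation check of the Bayesian proportionality fit: for each
#' seed, simulates one group, fits the model with missing-hatch-radius
#' imputation, and records the posterior means of `b` and `c` plus the
#' 95% credible-interval coverage of the true masked hatch radii.
#'
#' @param n_seeds Number of simulation replicates.
#' @param base_seed Replicate s uses seed `base_seed + s`.
#' @param n_individuals,true_b,true_c,missing_r0p_rate,sigma_length
#'   Generative conditions.
#' @param settings [mcmc_settings()] for each fit.
#' @return List: `per_seed` tibble (`seed`, `b_hat`, `c_hat`,
#'   `rel_err_b`, `rel_err_c`, `n_masked`, `n_covered`), `mare_b_pct`,
#'   `mare_c_pct` (mean absolute relative errors, percent), and
#'   `r0p_coverage_pct` (pooled over all masked fish).
#' @export
proportionality_recovery_study <- function(n_seeds = 20, base_seed = 0,
                                           n_individuals = 40,
                                           true_b = 150, true_c = 1.2,
                                           missing_r0p_rate = 0.3,
                                           sigma_length = 5,
                                           settings = mcmc_settings(
                                             chains = 4, iter = 1000,
                                             warmup = 500,
                                             on_nonconvergence = "warn")) {
  rows <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    cfg <- simulation_config(
      n_species = 1, n_individuals_per_species = n_individuals,
      true_b = true_b, true_c = true_c,
      missing_r0p_rate = missing_r0p_rate, sigma_length = sigma_length,
      seed = base_seed + s)
    sim <- simulate_dataset(cfg)
    st <- settings
    st$seed <- base_seed + 100L * s
    post <- suppressWarnings(
      fit_proportionality(sim$dataset$individuals, settings = st,
                          group_key = paste0("seed", s)))
    truth <- sim$truth$individuals
    masked <- colnames(post$imputed)
    covered <- vapply(masked, function(id) {
      ci <- quantile(post$imputed[, id], c(0.025, 0.975))
      tr <- truth$r0p_true[truth$individual_id == id]
      tr >= ci[1] && tr <= ci[2]
    }, logical(1))
    m <- colMeans(post$draws)
    rows[[s]] <- tibble(
      seed = cfg$seed, b_hat = m[["b"]], c_hat = m[["c"]],
      rel_err_b = abs(m[["b"]] / true_b - 1),
      rel_err_c = abs(m[["c"]] / true_c - 1),
      n_masked = length(masked), n_covered = sum(covered))
  }
  per_seed <- dplyr::bind_rows(rows)
  list(per_seed = per_seed,
       mare_b_pct = 100 * mean(per_seed$rel_err_b),
       mare_c_pct = 100 * mean(per_seed$rel_err_c),
       r0p_coverage_pct = 100 * sum(per_seed$n_covered) /
         sum(per_seed$n_masked))
}

#' Hierarchical Von Bertalanffy recovery study
#'
#' Simulates one group with known population growth parameters, feeds the
#' exact size-at-age trajectories (the back-calculation oracle output) to
#' the hierarchical fit, and reports relative errors of the population
#' posterior means.
#'
#' @param seed Simulation seed.
#' @param n_individuals Fish in the group.
#' @param pop_linf,pop_k True population parameters.
#' @param settings [mcmc_settings()] for the fit.
#' @return List: `linf_hat`, `k_hat`, `rel_err_linf`, `rel_err_k`,
#'   `n_individuals`.
#' @export
vb_recovery_study <- function(seed = 1, n_individuals = 20,
                              pop_linf = 400, pop_k = 0.4,
                              settings = mcmc_settings(
                                chains = 2, iter = 1500, warmup = 750,
                                on_nonconvergence = "warn")) {
  cfg <- simulation_config(
    n_species = 1, n_individuals_per_species = n_individuals,
    pop_linf = pop_linf, pop_k = pop_k, sigma_length = 0,
    missing_r0p_rate = 0, seed = seed)
  sim <- simulate_dataset(cfg)
  est <- dplyr::rename(sim$truth$lengths, length_mean = true_length)
  fd <- filter_for_hierarchical_fit(est, sim$dataset$individuals)
  pri <- vb_priors(linf_mean = pop_linf, linf_sd = pop_linf / 4,
                   k_mean = pop_k)
  post <- suppressWarnings(fit_vb_hierarchical(fd, pri, settings))
  m <- colMeans(post$population)
  list(linf_hat = m[["linf"]], k_hat = m[["k"]],
       rel_err_linf = abs(m[["linf"]] / pop_linf - 1),
       rel_err_k = abs(m[["k"]] / pop_k - 1),
       n_individuals = dplyr::n_distinct(fd$individual_id))
}

#' Direction-of-bias and credible-band overlap study
#'
#' For each seed: simulates a group under the default noisy conditions,
#' runs the full back-calculation (Bayesian proportionality fit plus
#' Modified Fry propagation), fits the hierarchical growth model on the
#' back-calculated size-at-age (which includes the age-0 hatch lengths)
#' and the plain model on size-at-capture only, then compares the two
#' population curves. Back-calculated fits are expected to yield higher
#' `K` and lower `Linf` on average — the curve is anchored near the origin
#' — while the 95% credible bands of the two curves should overlap across
#' ages.
#'
#' @param n_seeds Number of replicates.
#' @param base_seed Replicate s uses seed `base_seed + s`.
#' @param n_individuals Fish per replicate (must exceed 10 for the raw
#'   fit).
#' @param pop_linf,pop_k True population parameters.
#' @param settings [mcmc_settings()] for every fit.
#' @return List: `per_seed` tibble (`seed`, `k_bc`, `k_raw`, `linf_bc`,
#'   `linf_raw`, `overlap`), `mean_k_bc`, `mean_k_raw`, `mean_linf_bc`,
#'   `mean_linf_raw`, `overlap_pct` (percent of seeds with bands
#'   overlapping at every grid age).
#' @export
bias_direction_study <- function(n_seeds = 20, base_seed = 0,
                                 n_individuals = 20,
                                 pop_linf = 400, pop_k = 0.4,
                                 settings = mcmc_settings(
                                   chains = 2, iter = 1000, warmup = 500,
                                   on_nonconvergence = "warn")) {
  rows <- vector("list", n_seeds)
  pri <- vb_priors(linf_mean = pop_linf, linf_sd = pop_linf / 4,
                   k_mean = pop_k)
  for (s in seq_len(n_seeds)) {
    cfg <- simulation_config(
      n_species = 1, n_individuals_per_species = n_individuals,
      pop_linf = pop_linf, pop_k = pop_k, seed = base_seed + s)
    sim <- simulate_dataset(cfg)
    st <- settings
    st$seed <- base_seed + 100L * s
    prop_post <- suppressWarnings(
      fit_proportionality(sim$dataset$individuals, settings = st))
    est <- backcalculate_group(sim$dataset$individuals,
                               sim$dataset$increments, prop_post)
    fd <- filter_for_hierarchical_fit(est, sim$dataset$individuals)
    post_bc <- suppressWarnings(fit_vb_hierarchical(fd, pri, st))
    post_raw <- suppressWarnings(fit_vb_raw(sim$dataset$individuals, pri,
                                            st))
    cmp <- compare_growth_curves(post_bc, post_raw,
                                 0:max(sim$dataset$individuals$age_cpt))
    rows[[s]] <- tibble(
      seed = cfg$seed,
      k_bc = mean(post_bc$population$k),
      k_raw = mean(post_raw$population$k),
      linf_bc = mean(post_bc$population$linf),
      linf_raw = mean(post_raw$population$linf),
      overlap = attr(cmp, "global_overlap"))
  }
  per_seed <- dplyr::bind_rows(rows)
  list(per_seed = per_seed,
       mean_k_bc = mean(per_seed$k_bc),
       mean_k_raw = mean(per_seed$k_raw),
       mean_linf_bc = mean(per_seed$linf_bc),
       mean_linf_raw = mean(per_seed$linf_raw),
       overlap_pct = 100 * mean(per_seed$overlap))
}
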