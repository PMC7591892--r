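test_that("the Von Bertalanffy curve matches its defining identities", {
  expect_equal(vb_length(-0.5, 500, 0.3, -0.5), 0)
  expect_equal(vb_length(1, 500, log(2), 0), 250)  # half-saturation at ln2/K
  expect_lt(abs(vb_length(0 + 100 / 0.3, 500, 0.3, 0) - 500), 1e-6 * 500)
  # strictly increasing and bounded by Linf for K > 0
  set.seed(3)
  for (i in 1:20) {
    linf <- runif(1, 100, 900); k <- runif(1, 0.1, 1)
    t0 <- runif(1, -2, 0.5)
    tt <- seq(t0, t0 + 30, length.out = 100)
    L <- vb_length(tt, linf, k, t0)
    expect_true(all(diff(L) > 0))
    expect_true(all(L < linf))
  }
})

test_that("hierarchical-fit filters implement the five-individual and age rules", {
  est <- tibble::tibble(
    individual_id = rep(sprintf("f%02d", 1:6), each = 3),
    age_i = rep(0:2, 6), length_mean = runif(18, 10, 100),
    length_sd = 1)
  ind <- tibble::tibble(individual_id = sprintf("f%02d", 1:6),
                        age_cpt = c(3, 3, 3, 3, 2, 2))
  # two fish at age 2 leave only 4: group dropped
  expect_equal(nrow(filter_for_hierarchical_fit(est, ind)), 0)
  # all at age >= 3: everything retained, age-0 points included
  ind$age_cpt <- rep(4, 6)
  kept <- filter_for_hierarchical_fit(est, ind)
  expect_equal(dplyr::n_distinct(kept$individual_id), 6)
  expect_true(0 %in% kept$age_i)
  # empty input stays empty
  expect_equal(nrow(filter_for_hierarchical_fit(est[0, ], ind)), 0)
})

test_that("the hierarchical fit recovers population growth parameters", {
  cfg <- simulation_config(n_species = 1, n_individuals_per_species = 20,
                           pop_linf = 400, pop_k = 0.4, sigma_length = 0,
                           missing_r0p_rate = 0, seed = 11)
  sim <- simulate_dataset(cfg)
  est <- dplyr::rename(sim$truth$lengths, length_mean = true_length)
  est$length_sd <- 0
  fd <- filter_for_hierarchical_fit(est, sim$dataset$individuals)
  pri <- vb_priors(linf_mean = 400, linf_sd = 100, k_mean = 0.4)
  post <- fit_vb_hierarchical(fd, pri, fast_mcmc(seed = 6, iter = 1200,
                                                 warmup = 600))
  m <- colMeans(post$population)
  expect_lt(abs(m[["linf"]] / 400 - 1), 0.10)
  expect_lt(abs(m[["k"]] / 0.4 - 1), 0.10)
  expect_equal(length(post$individual), post$meta$n_individuals)
  expect_true(all(c("mu_linf", "k_pop", "t0_pop") %in%
                    post$diagnostics$parameter))
})

test_that("with no among-individual variance the individual posteriors shrink to the population", {
  cfg <- simulation_config(n_species = 1, n_individuals_per_species = 12,
                           pop_linf = 300, pop_k = 0.5, sd_linf = 0.01,
                           sd_logk = 0.001, sigma_length = 0,
                           missing_r0p_rate = 0, seed = 13)
  sim <- simulate_dataset(cfg)
  est <- dplyr::rename(sim$truth$lengths, length_mean = true_length)
  fd <- filter_for_hierarchical_fit(est, sim$dataset$individuals)
  pri <- vb_priors(linf_mean = 300, linf_sd = 80, k_mean = 0.5)
  post <- fit_vb_hierarchical(fd, pri, fast_mcmc(seed = 7),
                              use_length_sd = FALSE)
  pop_mean <- mean(post$population$linf)
  ind_means <- vapply(post$individual, function(d) mean(d$linf), numeric(1))
  expect_true(all(abs(ind_means / pop_mean - 1) < 0.05))
})

test_that("an informative prior is narrowed, not widened, by consistent data", {
  cfg <- simulation_config(n_species = 1, n_individuals_per_species = 6,
                           pop_linf = 350, pop_k = 0.45, sigma_length = 0,
                           missing_r0p_rate = 0, max_age = 9, seed = 17)
  sim <- simulate_dataset(cfg)
  est <- dplyr::rename(sim$truth$lengths, length_mean = true_length)
  fd <- filter_for_hierarchical_fit(est, sim$dataset$individuals,
                                    min_individuals = 5)
  pri <- vb_priors(linf_mean = 350, linf_sd = 80, k_mean = 0.45,
                   k_sdlog = 0.5)
  post <- fit_vb_hierarchical(fd, pri, fast_mcmc(seed = 8))
  expect_lt(sd(post$population$linf), 80)
  expect_lt(sd(log(post$population$k)), 0.5)
})

test_that("the raw-data fit enforces strict group size and is seed-deterministic", {
  ds <- toy_dataset(n = 10)
  expect_error(fit_vb_raw(ds$individuals, vb_priors()), "more than 10")

  cfg <- simulation_config(n_species = 1, n_individuals_per_species = 30,
                           pop_linf = 400, pop_k = 0.4, seed = 19)
  sim <- simulate_dataset(cfg)
  pri <- vb_priors(linf_mean = 400, linf_sd = 100, k_mean = 0.4)
  p1 <- fit_vb_raw(sim$dataset$individuals, pri, fast_mcmc(seed = 9))
  p2 <- fit_vb_raw(sim$dataset$individuals, pri, fast_mcmc(seed = 9))
  expect_identical(p1$population, p2$population)
  expect_lt(abs(mean(p1$population$linf) / 400 - 1), 0.15)
})

test_that("the convergence protocol logs nothing when the first fit converges", {
  cfg <- simulation_config(n_species = 1, n_individuals_per_species = 10,
                           sigma_length = 0, missing_r0p_rate = 0,
                           seed = 23)
  sim <- simulate_dataset(cfg)
  est <- dplyr::rename(sim$truth$lengths, length_mean = true_length)
  set.seed(99)
  est$length_mean <- est$length_mean + rnorm(nrow(est), 0, 2)
  est$length_sd <- 2
  fd <- filter_for_hierarchical_fit(est, sim$dataset$individuals)
  s <- mcmc_settings(chains = 2, iter = 2000, warmup = 1000, seed = 10,
                     rhat_threshold = 1.05, on_nonconvergence = "warn")
  res <- convergence_protocol(fd, vb_priors(linf_mean = 400, linf_sd = 100,
                                            k_mean = 0.4), s)
  expect_true(res$posterior$converged)
  expect_equal(nrow(res$action_log), 0)
  expect_equal(res$posterior$meta$dropped, character(0))
})

test_that("an impossible threshold exercises augmentation and individual removal", {
  cfg <- simulation_config(n_species = 1, n_individuals_per_species = 7,
                           sigma_length = 0, missing_r0p_rate = 0,
                           max_age = 5, seed = 29)
  sim <- simulate_dataset(cfg)
  est <- dplyr::rename(sim$truth$lengths, length_mean = true_length)
  fd <- filter_for_hierarchical_fit(est, sim$dataset$individuals)
  # R-hat is >= 1 by construction, so a threshold of 1.0 always retriggers
  s <- mcmc_settings(chains = 2, iter = 600, warmup = 300,
                     rhat_threshold = 1.0, seed = 11,
                     on_nonconvergence = "warn")
  expect_warning(
    res <- convergence_protocol(fd, vb_priors(linf_mean = 400,
                                              linf_sd = 100, k_mean = 0.4),
                                s, max_drop = 1),
    "non-convergent")
  expect_true(all(c("augment_iterations",
                    "drop_individual") %in% res$action_log$action))
  expect_equal(length(res$posterior$meta$dropped), 1)
  expect_equal(res$posterior$meta$n_individuals,
               dplyr::n_distinct(fd$individual_id) - 1)
})

test_that("credible-band comparison flags overlap and ordering correctly", {
  set.seed(31)
  a <- const_vb_posterior(400, 0.4, -0.1, jitter = 5)
  cmp_same <- compare_growth_curves(a, a, 0:8)
  expect_true(all(cmp_same$overlap))
  expect_true(attr(cmp_same, "global_overlap"))
  expect_true(attr(cmp_same, "bc_below_raw"))

  lo <- const_vb_posterior(100, 0.4, -0.1, jitter = 1)
  hi <- const_vb_posterior(1000, 0.4, -0.1, jitter = 1)
  cmp_far <- compare_growth_curves(lo, hi, 1:8)
  expect_false(any(cmp_far$overlap))
  expect_false(attr(cmp_far, "global_overlap"))
  expect_true(attr(cmp_far, "bc_below_raw"))
})
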