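test_that("capture-length and biological-intercept formulas match hand evaluation", {
  # identity case: capture radius equal to hatch radius
  expect_equal(predict_capture_length(2, 0.01, 0.01, 200, 1), 2)
  expect_equal(predict_capture_length(2, 0.01, 1, 200, 1), 200)
  expect_equal(predict_capture_length(2, 0.1, 1, 100, 2), 101)
  expect_error(predict_capture_length(2, -0.01, 1, 200, 1), "positive")

  expect_equal(biological_intercept_a(2, 0.01, 200, 1), 0)
  expect_equal(biological_intercept_a(2, 0.1, 100, 2), 1)
  expect_equal(biological_intercept_a(2, 0.1, 0, 2), 2)  # zero slope
  # a < L0p whenever b > 0
  set.seed(1)
  a <- biological_intercept_a(2, runif(100, 0.01, 0.2),
                              runif(100, 1, 300), runif(100, 0.5, 2))
  expect_true(all(a < 2))
})

test_that("Modified Fry interpolation passes through both anchors and a hand-computed midpoint", {
  # log-linear interpolation: exp(ln 2 + 0.5 ln 100) = 20
  expect_equal(modified_fry(200, 2, 1, 0.01, 0.1, 0), 20)
  expect_equal(modified_fry(200, 2, 1, 0.01, 0.01, 0), 2)
  expect_equal(modified_fry(200, 2, 1, 0.01, 1, 0), 200)

  set.seed(42)
  n <- 10000
  l0p <- runif(n, 1.5, 4.5)
  lcpt <- runif(n, 30, 900)
  r0p <- runif(n, 0.008, 0.14)
  rcpt <- runif(n, 0.2, 3.9)
  b <- runif(n, 10, 400)
  cc <- runif(n, 0.5, 2)
  a <- biological_intercept_a(l0p, r0p, b, cc)
  # endpoint identities to 1e-9 relative error
  at_hatch <- modified_fry(lcpt, l0p, rcpt, r0p, r0p, a)
  at_capture <- modified_fry(lcpt, l0p, rcpt, r0p, rcpt, a)
  expect_lt(max(abs(at_hatch - l0p) / l0p), 1e-9)
  expect_lt(max(abs(at_capture - lcpt) / lcpt), 1e-9)

  # strict monotonicity in radius for growing fish
  grow <- lcpt > l0p & rcpt > r0p
  for (i in sample(which(grow), 200)) {
    ri <- seq(r0p[i], rcpt[i], length.out = 25)
    li <- modified_fry(lcpt[i], l0p[i], rcpt[i], r0p[i], ri, a[i])
    expect_true(all(diff(li) > 0))
  }

  # log-domain violations yield NA, not errors
  expect_true(is.na(modified_fry(200, 2, 1, 0.01, 0.1, a = 250)))
  expect_true(is.na(modified_fry(200, 2, 0.01, 0.01, 0.1, a = 0)))
  expect_true(is.na(modified_fry(200, 2, 1, 0.01, -0.1, a = 0)))
})

test_that("noise-free closure: truth pushed through the pipeline returns truth", {
  cfg <- simulation_config(n_species = 1, n_individuals_per_species = 10,
                           sigma_length = 0, missing_r0p_rate = 0.3,
                           true_b = 180, true_c = 1.1, seed = 21)
  sim <- simulate_dataset(cfg)
  members <- sim$dataset$individuals
  r0p_true <- setNames(sim$truth$individuals$r0p_true,
                       sim$truth$individuals$individual_id)
  post <- point_mass_posterior(members, b = 180, c = 1.1,
                               r0p_values = r0p_true)
  est <- backcalculate_group(members, sim$dataset$increments, post)
  j <- dplyr::inner_join(est, sim$truth$lengths,
                         by = c("individual_id", "age_i"))
  expect_gt(nrow(j), 0)
  expect_lt(max(abs(j$length_mean - j$true_length), na.rm = TRUE), 1e-6)
  expect_true(all(j$length_sd[!is.na(j$length_sd)] == 0))
})

test_that("per-age summaries anchor exactly at hatching and capture", {
  ds <- toy_dataset(n = 6, r0p_known = c(TRUE, TRUE, TRUE, TRUE, FALSE,
                                         FALSE))
  members <- ds$individuals
  post <- fit_proportionality(members, settings = fast_mcmc(seed = 4),
                              group_key = "toy")
  est <- backcalculate_group(members, ds$increments, post)

  known <- members$individual_id[!is.na(members$radius_0p)]
  age0 <- est[est$age_i == 0 & est$individual_id %in% known, ]
  expect_equal(age0$length_mean, rep(2.5, nrow(age0)), tolerance = 1e-12)
  expect_equal(age0$length_sd, rep(0, nrow(age0)))

  at_cpt <- dplyr::inner_join(
    est, members[c("individual_id", "age_cpt", "length_cpt")],
    by = "individual_id")
  at_cpt <- at_cpt[at_cpt$age_i == at_cpt$age_cpt, ]
  expect_equal(at_cpt$length_mean, at_cpt$length_cpt, tolerance = 1e-12)
  expect_equal(at_cpt$length_sd, rep(0, nrow(at_cpt)))

  # intermediate ages carry positive propagated uncertainty
  mid <- est[est$age_i > 0, ]
  mid <- dplyr::anti_join(mid, at_cpt[c("individual_id", "age_i")],
                          by = c("individual_id", "age_i"))
  expect_true(all(mid$length_sd[!is.na(mid$length_sd)] > 0))

  # interpolation boundedness between the two anchors
  j <- dplyr::inner_join(est, members, by = "individual_id")
  j <- j[!is.na(j$length_mean), ]
  expect_true(all(j$length_mean >= pmin(j$length_0p, j$length_cpt) - 1e-9))
  expect_true(all(j$length_mean <=
                    pmax(j$length_0p, j$length_cpt) * 1.0 + 1e-9))

  # masked fish get no age-0 estimate (radius masked) but keep later ages
  masked <- members$individual_id[is.na(members$radius_0p)]
  expect_true(all(is.na(
    est$length_mean[est$individual_id %in% masked & est$age_i == 0])))
  expect_true(all(!is.na(
    est$length_mean[est$individual_id %in% masked & est$age_i > 0])))
})

test_that("the proportionality fit recovers generative parameters and imputes hatch radii", {
  cfg <- simulation_config(n_species = 1, n_individuals_per_species = 40,
                           true_b = 150, true_c = 1.2, sigma_length = 0.5,
                           missing_r0p_rate = 0.3, seed = 5)
  sim <- simulate_dataset(cfg)
  post <- fit_proportionality(sim$dataset$individuals,
                              settings = fast_mcmc(seed = 5, iter = 1500,
                                                   warmup = 750))
  m <- colMeans(post$draws)
  expect_lt(abs(m[["b"]] / 150 - 1), 0.10)
  expect_lt(abs(m[["c"]] / 1.2 - 1), 0.05)
  expect_true(all(post$draws$b > 0))
  expect_true(all(post$draws$sigma > 0))
  expect_true(all(post$imputed > 0))
  expect_equal(nrow(post$draws), post$n_draws)

  # most masked hatch radii fall inside their 95% credible interval
  truth <- sim$truth$individuals
  masked <- colnames(post$imputed)
  covered <- vapply(masked, function(id) {
    ci <- quantile(post$imputed[, id], c(0.025, 0.975))
    tr <- truth$r0p_true[truth$individual_id == id]
    tr >= ci[1] && tr <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.6)
})

test_that("the fit concentrates near one in the linear limit", {
  cfg <- simulation_config(n_species = 1, n_individuals_per_species = 35,
                           true_b = 200, true_c = 1, sigma_length = 0.5,
                           missing_r0p_rate = 0, seed = 12)
  sim <- simulate_dataset(cfg)
  post <- fit_proportionality(sim$dataset$individuals,
                              settings = fast_mcmc(seed = 2, iter = 1500,
                                                   warmup = 750))
  ci <- quantile(post$draws$c, c(0.025, 0.975))
  expect_lte(ci[1], 1)
  expect_gte(ci[2], 1)
})

test_that("ineligible inputs raise data errors", {
  ds <- toy_dataset(n = 5, r0p_known = c(TRUE, rep(FALSE, 4)))
  expect_error(fit_proportionality(ds$individuals, settings = fast_mcmc()),
               "at least 2 known")
  ds2 <- toy_dataset(n = 4)
  ds2$individuals$radius_cpt <- 1.5
  expect_error(fit_proportionality(ds2$individuals,
                                   settings = fast_mcmc()), "degenerate")
  ds3 <- toy_dataset(n = 4)
  ds3$individuals$length_0p <- c(2.5, 2.5, 3, 3)
  expect_error(fit_proportionality(ds3$individuals,
                                   settings = fast_mcmc()), "L0p")
})

test_that("run_backcalculation annotates eligible groups and skips the rest", {
  # species A eligible, species B has a single known hatch radius
  dsA <- toy_dataset(n = 6)
  dsB <- toy_dataset(n = 5, r0p_known = c(TRUE, rep(FALSE, 4)))
  dsB$individuals$species <- "droppedia"
  dsB$individuals$individual_id <- paste0("b_", dsB$individuals$individual_id)
  dsB$increments$individual_id <- paste0("b_", dsB$increments$individual_id)
  ds <- growth_dataset(
    dplyr::bind_rows(dsA$individuals, dsB$individuals),
    dplyr::bind_rows(dsA$increments, dsB$increments))

  res <- run_backcalculation(ds, "species", settings = fast_mcmc(seed = 3))
  expect_setequal(res$report$status, c("ok", "skipped"))
  skipped <- res$report[res$report$status == "skipped", ]
  expect_equal(skipped$reason, "insufficient_r0p")

  inc <- res$dataset$increments
  b_rows <- inc[inc$individual_id %in% dsB$increments$individual_id, ]
  expect_true(all(is.na(b_rows$li_sp_m)))
  a_rows <- inc[inc$individual_id %in% dsA$increments$individual_id &
                  !is.na(inc$radius_i), ]
  expect_false(anyNA(a_rows$li_sp_m))

  # single-location data: species and species-by-location member sets match
  res2 <- run_backcalculation(ds, "both", settings = fast_mcmc(seed = 3))
  rep2 <- res2$report[res2$report$status == "ok", ]
  expect_equal(rep2$n_members[rep2$grouping == "species"],
               rep2$n_members[rep2$grouping == "species_by_location"])

  # empty dataset
  empty <- growth_dataset(ds$individuals[0, ], ds$increments[0, ])
  res3 <- run_backcalculation(empty, "species", settings = fast_mcmc())
  expect_equal(nrow(res3$report), 0)
  expect_equal(nrow(res3$estimates), 0)
})
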