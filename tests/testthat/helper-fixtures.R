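# Shared fixtures: everything is generated in code at test time.

# Short chains for unit tests; recovery checks at realistic sizes live in
# the acceptance suite.
fast_mcmc <- function(seed = 1, chains = 2, iter = 800, warmup = 400) {
  mcmc_settings(chains = chains, iter = iter, warmup = warmup,
                seed = seed, on_nonconvergence = "warn")
}

# Minimal well-formed long-format CSV: one individual, ages 0..2.
toy_csv_lines <- function() {
  c(
    "Family,Genus,Species,ID,Age_i,R_i,Age_cpt,R_cpt,L_cpt,L_0p,R_0p,Li_sp_m,Li_sp_sd,Li_sploc_m,Li_sploc_sd,Weight,Location,Observer",
    "Acanthuridae,Acanthurus,triostegus,fish1,0,0.05,2,1.2,150,2.5,0.05,NA,NA,NA,NA,34.2,Moorea,reader_a",
    "Acanthuridae,Acanthurus,triostegus,fish1,1,0.70,2,1.2,150,2.5,0.05,NA,NA,NA,NA,34.2,Moorea,reader_a",
    "Acanthuridae,Acanthurus,triostegus,fish1,2,1.20,2,1.2,150,2.5,0.05,NA,NA,NA,NA,34.2,Moorea,reader_a"
  )
}

write_toy_csv <- function(lines = toy_csv_lines()) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Hand-built dataset: n fish of one species, simple geometric trajectories
# satisfying every schema invariant. r0p_known marks which fish keep their
# hatch radius.
toy_dataset <- function(n = 5, age_cpt = rep(3, n),
                        r0p_known = rep(TRUE, n), location = "Moorea") {
  stopifnot(length(age_cpt) == n, length(r0p_known) == n)
  b <- 120; cc <- 1; l0p <- 2.5
  ind <- list(); inc <- list()
  for (i in seq_len(n)) {
    id <- sprintf("toy_%02d", i)
    r0p <- 0.04 + 0.005 * i
    ages <- 0:age_cpt[i]
    radius <- r0p + 0.4 * ages * (1 + 0.03 * i)
    len <- l0p - b * r0p^cc + b * radius^cc
    ind[[i]] <- tibble::tibble(
      individual_id = id, family = "Toyidae", genus = "Toyus",
      species = "examplaris", location = location,
      age_cpt = age_cpt[i], radius_cpt = radius[length(radius)],
      length_cpt = len[length(len)], length_0p = l0p,
      radius_0p = if (r0p_known[i]) r0p else NA_real_,
      weight = NA_real_, observer = "tester")
    radius_out <- radius
    if (!r0p_known[i]) radius_out[1] <- NA_real_
    inc[[i]] <- tibble::tibble(individual_id = id, age_i = ages,
                               radius_i = radius_out)
  }
  growth_dataset(dplyr::bind_rows(ind), dplyr::bind_rows(inc),
                 provenance = "toy_dataset fixture")
}

# Degenerate vb_posterior with all draws at fixed parameter values, for
# curve-comparison tests.
const_vb_posterior <- function(linf, k, t0, n_draws = 200, jitter = 0) {
  pop <- tibble::tibble(
    linf = linf + jitter * stats::rnorm(n_draws),
    k = rep(k, n_draws), t0 = rep(t0, n_draws),
    sigma = rep(1, n_draws))
  structure(list(population = pop, individual = NULL,
                 diagnostics = tibble::tibble(parameter = character(),
                                              rhat = numeric(),
                                              ess = numeric()),
                 converged = TRUE,
                 meta = list(kind = "raw", n_individuals = n_draws,
                             n_obs = n_draws, individuals = character(),
                             dropped = character())),
            class = "vb_posterior")
}
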