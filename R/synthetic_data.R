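#' Configuration for the synthetic growth-data generator
#'
#' Defines the generative model for a synthetic otolith increment dataset.
#' Individual growth follows a Von Bertalanffy curve whose parameters vary
#' among fish around population values; the otolith radius is coupled to
#' body length through the power-law biological-intercept relationship
#' `L = L0p - b * R0p^c + b * R^c`, so that the back-calculation model is
#' exactly well-specified and parameter recovery is a meaningful test.
#' Observation noise is applied to length at capture only; hatch radii are
#' masked completely at random at rate `missing_r0p_rate`.
#'
#' @param n_species Number of species to simulate.
#' @param n_individuals_per_species Fish per species.
#' @param true_b Proportionality coefficient b (mm per mm^c), recycled
#'   across species.
#' @param true_c Proportionality exponent c (dimensionless), recycled.
#' @param length_0p Total length at hatching L0p (mm), recycled across
#'   species. Defaults to 2.5 mm, within the 1.45--4.25 mm range typical of
#'   reef-fish larvae.
#' @param r0p_mean,r0p_sd Mean and sd (mm) of the truncated-positive normal
#'   hatch-radius population; defaults sit inside the 0.008--0.136 mm range
#'   observed for sagittal otolith nuclei.
#' @param pop_linf Population asymptotic length L-infinity (mm).
#' @param pop_k Population growth coefficient K (1/yr).
#' @param sd_linf Among-individual sd of L-infinity (mm); individual values
#'   are normal, truncated above `length_0p`.
#' @param sd_logk Among-individual sd of log K (individual K lognormal
#'   around `pop_k`).
#' @param sigma_length Observation noise sd on length at capture (mm).
#' @param missing_r0p_rate Probability a fish's hatch radius is masked,
#'   in `[0, 1)`.
#' @param max_age Maximum age at capture (years, >= 3); ages at capture are
#'   integers drawn uniformly on `[2, max_age]`.
#' @param radius_noise_cv Optional multiplicative lognormal noise CV on
#'   increment radii (0 = body-proportional coupling holds exactly; the
#'   default). Nonzero values support robustness studies.
#' @param seed Integer seed making [simulate_dataset()] fully reproducible.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_species = 2,
                              n_individuals_per_species = 20,
                              true_b = 200,
                              true_c = 1,
                              length_0p = 2.5,
                              r0p_mean = 0.05,
                              r0p_sd = 0.02,
                              pop_linf = 400,
                              pop_k = 0.4,
                              sd_linf = 20,
                              sd_logk = 0.15,
                              sigma_length = 5,
                              missing_r0p_rate = 0.3,
                              max_age = 8,
                              radius_noise_cv = 0,
                              seed = 1) {
  cfg <- list(
    n_species = as.integer(n_species),
    n_individuals_per_species = as.integer(n_individuals_per_species),
    true_b = true_b, true_c = true_c, length_0p = length_0p,
    r0p_mean = r0p_mean, r0p_sd = r0p_sd,
    pop_linf = pop_linf, pop_k = pop_k,
    sd_linf = sd_linf, sd_logk = sd_logk,
    sigma_length = sigma_length,
    missing_r0p_rate = missing_r0p_rate,
    max_age = as.integer(max_age),
    radius_noise_cv = radius_noise_cv,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_species >= 1, cfg$n_individuals_per_species >= 1,
    all(cfg$true_b > 0), all(cfg$true_c > 0), all(cfg$length_0p > 0),
    cfg$r0p_mean > 0, cfg$r0p_sd >= 0,
    cfg$pop_linf > max(cfg$length_0p), cfg$pop_k > 0,
    cfg$sd_linf >= 0, cfg$sd_logk >= 0, cfg$sigma_length >= 0,
    cfg$missing_r0p_rate >= 0, cfg$missing_r0p_rate < 1,
    cfg$max_age >= 3, cfg$radius_noise_cv >= 0
  )
  structure(cfg, class = "simulation_config")
}

# truncated-normal draw on (lower, Inf) by rejection; cheap at these scales
rnorm_trunc <- function(n, mean, sd, lower = 0) {
  if (sd == 0) {
    if (any(mean <= lower)) stop("degenerate truncated draw below bound")
    return(rep(mean, length.out = n))
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (try in 1:1000) {
      x <- rnorm(1, mean, sd)
      if (x > lower) break
      x <- NA_real_
    }
    if (is.na(x)) stop("truncated-normal rejection failed after 1000 tries")
    out[i] <- x
  }
  out
}

#' Simulate one individual fish
#'
#' Draws individual Von Bertalanffy parameters around the population values,
#' anchors the curve so that length at age zero equals the species hatch
#' length (`t0_j = log(1 - L0p / Linf_j) / K_j`), evaluates true lengths at
#' integer ages up to a uniformly drawn capture age, and converts lengths to
#' otolith radii by inverting the biological-intercept power law at the
#' individual's own hatch radius. The observed capture length is the true
#' length plus Gaussian noise, floored just above the hatch length.
#'
#' @param cfg A [simulation_config()]. Uses the current RNG state; callers
#'   seed it (as [simulate_dataset()] does).
#' @param species_idx Species index (selects recycled per-species values).
#' @param individual_id Identifier for the emitted records.
#' @return List with `individual` (one-row tibble), `increments` (tibble of
#'   age/radius rows including age 0 and the capture age), and `truth`
#'   (one-row tibble of generative parameters) plus `truth_lengths`
#'   (tibble of true length and radius at every age).
#' @export
simulate_individual <- function(cfg, species_idx = 1L,
                                individual_id = "fish_1") {
  stopifnot(inherits(cfg, "simulation_config"))
  b <- rep(cfg$true_b, length.out = cfg$n_species)[species_idx]
  cc <- rep(cfg$true_c, length.out = cfg$n_species)[species_idx]
  l0p <- rep(cfg$length_0p, length.out = cfg$n_species)[species_idx]

  linf_j <- rnorm_trunc(1, cfg$pop_linf, cfg$sd_linf, lower = l0p * 1.5)
  k_j <- cfg$pop_k * exp(rnorm(1, 0, cfg$sd_logk))
  t0_j <- log(1 - l0p / linf_j) / k_j
  age_cpt <- sample(2:cfg$max_age, 1)

  ages <- 0:age_cpt
  true_len <- vb_length(ages, linf_j, k_j, t0_j)
  r0p_j <- rnorm_trunc(1, cfg$r0p_mean, cfg$r0p_sd, lower = 1e-4)
  radius <- ((true_len - l0p) / b + r0p_j^cc)^(1 / cc)
  radius[1] <- r0p_j  # exact hatch anchor (age 0)
  if (cfg$radius_noise_cv > 0) {
    noise <- exp(rnorm(length(ages) - 1, 0, cfg$radius_noise_cv))
    radius[-1] <- radius[-1] * noise
    radius <- cummax(radius)  # keep trajectories monotone
  }
  true_lcpt <- true_len[length(true_len)]
  obs_lcpt <- max(true_lcpt + rnorm(1, 0, cfg$sigma_length), l0p + 0.01)

  individual <- tibble(
    individual_id = individual_id,
    family = paste0("SimFamily", species_idx),
    genus = "Simulus",
    species = paste0("synthetica_", species_idx),
    location = "SimIsland",
    age_cpt = age_cpt,
    radius_cpt = radius[length(radius)],
    length_cpt = obs_lcpt,
    length_0p = l0p,
    radius_0p = r0p_j,
    weight = NA_real_,
    observer = "simulator"
  )
  increments <- tibble(individual_id = individual_id, age_i = ages,
                       radius_i = radius)
  truth <- tibble(
    individual_id = individual_id, species_idx = species_idx,
    linf = linf_j, k = k_j, t0 = t0_j,
    r0p_true = r0p_j, true_length_cpt = true_lcpt,
    b = b, c = cc, length_0p = l0p
  )
  truth_lengths <- tibble(individual_id = individual_id, age_i = ages,
                          true_length = true_len, true_radius = radius)
  list(individual = individual, increments = increments,
       truth = truth, truth_lengths = truth_lengths)
}

#' Simulate a full growth dataset with retained ground truth
#'
#' Generates `n_species * n_individuals_per_species` fish under
#' [simulate_individual()], then masks hatch radii completely at random at
#' rate `missing_r0p_rate` via [apply_missingness()] (always leaving at
#' least two known hatch radii per species-location group). Identical
#' configuration and seed give byte-identical output.
#'
#' @param cfg A [simulation_config()].
#' @return List with `dataset` (a [growth_dataset()] that passes
#'   [validate_dataset()] with an empty report) and `truth` (list:
#'   `individuals` tibble of generative parameters with a `masked` flag,
#'   `lengths` tibble of true length/radius at every age, and the
#'   generative `b`, `c` vectors).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  sims <- list()
  idx <- 0L
  for (sp in seq_len(cfg$n_species)) {
    for (i in seq_len(cfg$n_individuals_per_species)) {
      idx <- idx + 1L
      id <- sprintf("sim_%02d_%03d", sp, i)
      sims[[idx]] <- simulate_individual(cfg, sp, id)
    }
  }
  ds <- growth_dataset(
    dplyr::bind_rows(lapply(sims, `[[`, "individual")),
    dplyr::bind_rows(lapply(sims, `[[`, "increments")),
    provenance = paste0("otogrow simulate_dataset seed=", cfg$seed)
  )
  truth_ind <- dplyr::bind_rows(lapply(sims, `[[`, "truth"))
  truth_len <- dplyr::bind_rows(lapply(sims, `[[`, "truth_lengths"))

  masked_ids <- character()
  if (cfg$missing_r0p_rate > 0) {
    ds <- apply_missingness(ds, cfg$missing_r0p_rate)
    masked_ids <- ds$individuals$individual_id[is.na(ds$individuals$radius_0p)]
  }
  truth_ind$masked <- truth_ind$individual_id %in% masked_ids
  list(dataset = ds,
       truth = list(individuals = truth_ind, lengths = truth_len,
                    b = rep(cfg$true_b, length.out = cfg$n_species),
                    c = rep(cfg$true_c, length.out = cfg$n_species)))
}

#' Mask hatch radii completely at random
#'
#' Masks `radius_0p` (and the corresponding age-0 increment radius) of
#' individuals selected at random, while guaranteeing that every
#' species-location group keeps at least two known hatch radii — the
#' minimum for the back-calculation fit. Within each group the number
#' masked is binomial at `rate`, capped at (group size - 2).
#'
#' @param ds A [growth_dataset()].
#' @param rate Masking probability in `[0, 1)`.
#' @return The masked [growth_dataset()]. Uses the current RNG state.
#' @export
apply_missingness <- function(ds, rate) {
  stopifnot(inherits(ds, "growth_dataset"), rate >= 0, rate < 1)
  if (rate == 0) return(ds)
  ind <- ds$individuals
  key <- paste(ind$genus, ind$species, ind$location, sep = "|")
  masked <- character()
  for (g in unique(key)) {
    ids <- ind$individual_id[key == g & !is.na(ind$radius_0p)]
    n <- length(ids)
    if (n < 2) {
      abort(paste0("group ", dQuote(g), " has fewer than 2 known hatch radii;",
                   " cannot mask while keeping the group fittable"))
    }
    m <- min(rbinom(1, n, rate), n - 2L)
    if (m > 0) masked <- c(masked, sample(ids, m))
  }
  ds$individuals$radius_0p[ds$individuals$individual_id %in% masked] <- NA_real_
  hit <- ds$increments$individual_id %in% masked & ds$increments$age_i == 0
  ds$increments$radius_i[hit] <- NA_real_
  ds
}
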