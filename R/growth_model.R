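#' Von Bertalanffy length at age
#'
#' Evaluates `L(t) = Linf * (1 - exp(-K * (t - t0)))`: asymptotic growth
#' toward `Linf` at rate `K`, with `t0` the theoretical age at zero length.
#'
#' @param t Age (years). Vectorized.
#' @param linf Asymptotic average length (mm).
#' @param k Growth coefficient (1/yr).
#' @param t0 Age at zero length (yr).
#' @return Length (mm).
#' @export
vb_length <- function(t, linf, k, t0) {
  linf * (1 - exp(-k * (t - t0)))
}

#' Priors for the Von Bertalanffy fits
#'
#' Informative priors are supplied per group (in practice extracted from a
#' life-history database such as FishBase): a truncated normal on `Linf`,
#' a lognormal on `K`, and a normal on `t0`. Hierarchical spread and
#' residual scales get half-normal hyperpriors; their default scales adapt
#' to the `Linf` prior so the same spec works across species of very
#' different sizes.
#'
#' @param linf_mean,linf_sd Normal prior on Linf (mm), truncated at 0.
#' @param k_mean Prior median of K (1/yr); the prior on `log K` is
#'   `Normal(log(k_mean), k_sdlog)`.
#' @param k_sdlog Prior sd of `log K`.
#' @param t0_mean,t0_sd Normal prior on t0 (yr).
#' @param sd_linf_scale Half-normal scale for the among-individual sd of
#'   Linf; defaults to `linf_sd`.
#' @param sd_logk_scale Half-normal scale for the among-individual sd of
#'   log K.
#' @param sigma_scale Half-normal scale for the residual sd (mm); defaults
#'   to `0.1 * linf_mean`.
#' @return A `vb_priors` list.
#' @export
vb_priors <- function(linf_mean = 400, linf_sd = 100,
                      k_mean = 0.4, k_sdlog = 0.5,
                      t0_mean = 0, t0_sd = 1,
                      sd_linf_scale = linf_sd,
                      sd_logk_scale = 0.5,
                      sigma_scale = 0.1 * linf_mean) {
  stopifnot(linf_mean > 0, linf_sd > 0, k_mean > 0, k_sdlog > 0, t0_sd > 0)
  structure(list(linf_mean = linf_mean, linf_sd = linf_sd,
                 k_mean = k_mean, k_sdlog = k_sdlog,
                 t0_mean = t0_mean, t0_sd = t0_sd,
                 sd_linf_scale = sd_linf_scale,
                 sd_logk_scale = sd_logk_scale,
                 sigma_scale = sigma_scale),
            class = "vb_priors")
}

#' Filter back-calculated estimates for the hierarchical growth fit
#'
#' Keeps individuals whose age at capture exceeds two years (younger fish
#' contribute too few increments to inform an individual curve) and keeps
#' the group only if at least five such individuals remain. Age-0 points
#' (the hatch length) are retained in the fitted data, anchoring the curve
#' near the origin.
#'
#' @param estimates Back-calculated estimates tibble (from
#'   [backcalculate_group()]): `individual_id`, `age_i`, `length_mean`,
#'   `length_sd`.
#' @param individuals Individuals tibble carrying `individual_id`,
#'   `age_cpt`.
#' @param min_individuals Minimum individuals per group (default 5).
#' @param min_age_cpt Individuals must satisfy `age_cpt > min_age_cpt`
#'   (default 2, i.e. age at capture of three or more).
#' @return The fit-ready subset of `estimates` (zero rows if the group
#'   fails the size rule), with an `age_cpt` column joined on.
#' @export
filter_for_hierarchical_fit <- function(estimates, individuals,
                                        min_individuals = 5,
                                        min_age_cpt = 2) {
  est <- dplyr::inner_join(as_tibble(estimates),
                           as_tibble(individuals)[c("individual_id",
                                                    "age_cpt")],
                           by = "individual_id")
  est <- est[est$age_cpt > min_age_cpt & !is.na(est$length_mean), ]
  if (dplyr::n_distinct(est$individual_id) < min_individuals) {
    return(est[0, ])
  }
  est
}

VB_HIER_MODEL <- "
model {
  mu_linf ~ dnorm(linf_mean, pow(linf_sd, -2)) T(0,)
  mu_logk ~ dnorm(log(k_mean), pow(k_sdlog, -2))
  t0_pop ~ dnorm(t0_mean, pow(t0_sd, -2))
  sd_linf ~ dnorm(0, pow(sd_linf_scale, -2)) T(0,)
  sd_logk ~ dnorm(0, pow(sd_logk_scale, -2)) T(0,)
  sigma ~ dnorm(0, pow(sigma_scale, -2)) T(0,)
  k_pop <- exp(mu_logk)
  for (j in 1:J) {
    linf[j] ~ dnorm(mu_linf, pow(sd_linf, -2)) T(0,)
    logk[j] ~ dnorm(mu_logk, pow(sd_logk, -2))
    k[j] <- exp(logk[j])
  }
  for (n in 1:N) {
    mu[n] <- linf[ind[n]] * (1 - exp(-k[ind[n]] * (age[n] - t0_pop)))
    L[n] ~ dnorm(mu[n], pow(sigma * sigma + v_known[n], -1))
  }
}"

VB_RAW_MODEL <- "
model {
  linf ~ dnorm(linf_mean, pow(linf_sd, -2)) T(0,)
  logk ~ dnorm(log(k_mean), pow(k_sdlog, -2))
  t0 ~ dnorm(t0_mean, pow(t0_sd, -2))
  sigma ~ dnorm(0, pow(sigma_scale, -2)) T(0,)
  k <- exp(logk)
  for (n in 1:N) {
    mu[n] <- linf * (1 - exp(-k * (age[n] - t0)))
    L[n] ~ dnorm(mu[n], pow(sigma, -2))
  }
}"

new_vb_posterior <- function(population, individual, diagnostics, converged,
                             meta) {
  structure(list(population = population, individual = individual,
                 diagnostics = diagnostics, converged = converged,
                 meta = meta),
            class = "vb_posterior")
}

#' @export
print.vb_posterior <- function(x, ...) {
  m <- colMeans(x$population)
  cat("<vb_posterior> ", x$meta$kind, " fit, ", nrow(x$population),
      " draws, ", x$meta$n_individuals, " individuals, ",
      x$meta$n_obs, " observations\n", sep = "")
  cat(sprintf("  Linf = %.1f mm, K = %.3f /yr, t0 = %.3f yr (posterior means)\n",
              m[["linf"]], m[["k"]], m[["t0"]]))
  invisible(x)
}

#' Hierarchical Bayesian Von Bertalanffy fit on back-calculated sizes
#'
#' Back-calculated size-at-age points within one fish are strongly
#' auto-correlated, so the model fits an individual growth curve per fish —
#' `Linf_j` normal and `log K_j` normal around population means — together
#' with the population-level curve those means define. `t0` is shared at
#' the population level (few points per fish leave individual `t0`
#' unidentifiable). The per-point back-calculation sd can enter the
#' likelihood as known additive measurement variance.
#'
#' @param data Fit-ready tibble (see [filter_for_hierarchical_fit()]):
#'   `individual_id`, `age_i`, `length_mean`, and optionally `length_sd`.
#' @param priors A [vb_priors()].
#' @param settings An [mcmc_settings()].
#' @param use_length_sd Add `length_sd^2` to the residual variance per
#'   point (default `TRUE`).
#' @return A `vb_posterior`: `population` (tibble of draws of `linf`, `k`,
#'   `t0`, `sigma`, `sd_linf`, `sd_logk`), `individual` (list of per-fish
#'   draw tibbles `linf`, `k`), `diagnostics`, `converged`, `meta`.
#' @export
fit_vb_hierarchical <- function(data, priors = vb_priors(),
                                settings = mcmc_settings(),
                                use_length_sd = TRUE) {
  data <- as_tibble(data)
  stopifnot(all(c("individual_id", "age_i", "length_mean") %in% names(data)))
  data <- data[!is.na(data$length_mean), ]
  ids <- sort(unique(data$individual_id))
  v_known <- if (use_length_sd && "length_sd" %in% names(data)) {
    ifelse(is.na(data$length_sd), 0, data$length_sd^2)
  } else rep(0, nrow(data))
  jdata <- list(
    N = nrow(data), J = length(ids),
    ind = match(data$individual_id, ids),
    age = data$age_i, L = data$length_mean, v_known = v_known,
    linf_mean = priors$linf_mean, linf_sd = priors$linf_sd,
    k_mean = priors$k_mean, k_sdlog = priors$k_sdlog,
    t0_mean = priors$t0_mean, t0_sd = priors$t0_sd,
    sd_linf_scale = priors$sd_linf_scale,
    sd_logk_scale = priors$sd_logk_scale,
    sigma_scale = priors$sigma_scale
  )
  monitor <- c("mu_linf", "k_pop", "t0_pop", "sigma", "sd_linf", "sd_logk",
               paste0("linf[", seq_along(ids), "]"),
               paste0("k[", seq_along(ids), "]"))
  inits <- function(ch) list(mu_linf = priors$linf_mean,
                             mu_logk = log(priors$k_mean),
                             t0_pop = priors$t0_mean)
  samples <- run_jags(VB_HIER_MODEL, jdata, monitor, settings, inits)
  diag <- mcmc_diagnostics(samples)
  core <- c("mu_linf", "k_pop", "t0_pop", "sigma")
  converged <- all(diag$rhat[diag$parameter %in% core] <=
                     settings$rhat_threshold, na.rm = TRUE)
  dm <- draws_matrix(samples)
  population <- tibble(linf = dm[, "mu_linf"], k = dm[, "k_pop"],
                       t0 = dm[, "t0_pop"], sigma = dm[, "sigma"],
                       sd_linf = dm[, "sd_linf"], sd_logk = dm[, "sd_logk"])
  individual <- lapply(seq_along(ids), function(j) {
    tibble(linf = dm[, paste0("linf[", j, "]")],
           k = dm[, paste0("k[", j, "]")])
  })
  names(individual) <- ids
  new_vb_posterior(population, individual, diag, converged,
                   meta = list(kind = "hierarchical",
                               n_individuals = length(ids),
                               n_obs = nrow(data),
                               iter = settings$iter,
                               warmup = settings$warmup,
                               individuals = ids,
                               dropped = character()))
}

#' Plain Bayesian Von Bertalanffy fit on size-at-capture data
#'
#' Non-hierarchical fit of the growth curve to one (age, length) point per
#' fish — the raw-data comparison model. Requires more than 10 individuals;
#' with a single point per fish, smaller groups cannot constrain three
#' parameters. Warns when the age range spans fewer than 3 distinct ages.
#'
#' @param individuals Individuals tibble: `individual_id`, `age_cpt`,
#'   `length_cpt`.
#' @param priors A [vb_priors()].
#' @param settings An [mcmc_settings()].
#' @return A `vb_posterior` (no `individual` draws).
#' @export
fit_vb_raw <- function(individuals, priors = vb_priors(),
                       settings = mcmc_settings()) {
  individuals <- as_tibble(individuals)
  if (nrow(individuals) <= 10)
    abort(paste0("raw Von Bertalanffy fit requires more than 10 individuals",
                 " (got ", nrow(individuals), ")"))
  if (dplyr::n_distinct(individuals$age_cpt) < 3)
    warn("fewer than 3 distinct capture ages; growth parameters may be weakly identified")
  jdata <- list(
    N = nrow(individuals),
    age = individuals$age_cpt, L = individuals$length_cpt,
    linf_mean = priors$linf_mean, linf_sd = priors$linf_sd,
    k_mean = priors$k_mean, k_sdlog = priors$k_sdlog,
    t0_mean = priors$t0_mean, t0_sd = priors$t0_sd,
    sigma_scale = priors$sigma_scale
  )
  monitor <- c("linf", "k", "t0", "sigma")
  inits <- function(ch) list(linf = priors$linf_mean,
                             logk = log(priors$k_mean), t0 = priors$t0_mean)
  samples <- run_jags(VB_RAW_MODEL, jdata, monitor, settings, inits)
  diag <- mcmc_diagnostics(samples)
  converged <- all(diag$rhat[diag$parameter %in% monitor] <=
                     settings$rhat_threshold, na.rm = TRUE)
  dm <- draws_matrix(samples)
  new_vb_posterior(
    tibble(linf = dm[, "linf"], k = dm[, "k"], t0 = dm[, "t0"],
           sigma = dm[, "sigma"]),
    individual = NULL, diagnostics = diag, converged = converged,
    meta = list(kind = "raw", n_individuals = nrow(individuals),
                n_obs = nrow(individuals), iter = settings$iter,
                warmup = settings$warmup,
                individuals = individuals$individual_id,
                dropped = character()))
}

#' Fit with the convergence-retry protocol
#'
#' Runs a Von Bertalanffy fit; if any monitored R-hat exceeds the
#' threshold, refits with iterations raised to 4,000 (warmup 2,000); if
#' convergence still fails, removes the individuals whose parameters carry
#' the worst R-hat values — an automated stand-in for inspecting MCMC chain
#' plots — one at a time (up to `max_drop`), refitting after each removal.
#' Every step is recorded in an action log.
#'
#' @param data Fit-ready back-calculated tibble (hierarchical fit input).
#' @param priors A [vb_priors()].
#' @param settings An [mcmc_settings()].
#' @param max_drop Maximum individuals removed (default 3).
#' @param use_length_sd Passed to [fit_vb_hierarchical()].
#' @return List: `posterior` (a `vb_posterior`; its `meta$dropped` names
#'   removed individuals) and `action_log` (tibble of `step`, `action`,
#'   `detail`, `max_rhat`). Errors if still non-convergent after the cap
#'   and `settings$on_nonconvergence` is `"error"`.
#' @export
convergence_protocol <- function(data, priors = vb_priors(),
                                 settings = mcmc_settings(), max_drop = 3,
                                 use_length_sd = TRUE) {
  data <- as_tibble(data)
  log <- list()
  step <- 0L
  core_rhat <- function(post) {
    max(post$diagnostics$rhat, na.rm = TRUE)
  }
  empty_log <- tibble(step = integer(), action = character(),
                      detail = character(), max_rhat = numeric())
  fit <- fit_vb_hierarchical(data, priors, settings, use_length_sd)
  if (fit$converged) {
    return(list(posterior = fit, action_log = empty_log))
  }
  # escalate iterations
  aug <- settings
  aug$iter <- max(4000L, settings$iter)
  aug$warmup <- max(2000L, settings$warmup)
  fit <- fit_vb_hierarchical(data, priors, aug, use_length_sd)
  step <- step + 1L
  log[[step]] <- tibble(step = step, action = "augment_iterations",
                        detail = sprintf("iter=%d warmup=%d", aug$iter,
                                         aug$warmup),
                        max_rhat = core_rhat(fit))
  dropped <- character()
  while (!fit$converged && length(dropped) < max_drop) {
    diag <- fit$diagnostics
    ids <- fit$meta$individuals
    per_ind <- vapply(seq_along(ids), function(j) {
      pars <- paste0(c("linf[", "k["), j, "]")
      max(diag$rhat[diag$parameter %in% pars], na.rm = TRUE)
    }, numeric(1))
    worst <- ids[which.max(per_ind)]
    dropped <- c(dropped, worst)
    data <- data[data$individual_id != worst, ]
    fit <- fit_vb_hierarchical(data, priors, aug, use_length_sd)
    step <- step + 1L
    log[[step]] <- tibble(step = step, action = "drop_individual",
                          detail = worst, max_rhat = core_rhat(fit))
  }
  fit$meta$dropped <- dropped
  if (!fit$converged) {
    msg <- sprintf("hierarchical fit non-convergent after %d augmentations and %d removals (max R-hat %.3f)",
                   1L, length(dropped), core_rhat(fit))
    if (settings$on_nonconvergence == "error") abort(msg) else warn(msg)
  }
  list(posterior = fit, action_log = dplyr::bind_rows(c(list(empty_log),
                                                        log)))
}

#' Compare population growth curves from two posteriors
#'
#' Evaluates both posterior population curves on an age grid and reports
#' per-age medians and 95% credible bands, whether the bands intersect at
#' each age, and whether the back-calculated median curve lies below the
#' raw-data median at every age (back-calculated fits include hatch-length
#' points near the origin, which typically lowers `Linf` and raises `K`).
#'
#' @param post_bc `vb_posterior` fitted on back-calculated size-at-age.
#' @param post_raw `vb_posterior` fitted on size-at-capture data.
#' @param ages Numeric age grid (years).
#' @param level Credible level for the bands (default 0.95).
#' @return Tibble with one row per grid age: `age`, `bc_median`, `bc_lo`,
#'   `bc_hi`, `raw_median`, `raw_lo`, `raw_hi`, `overlap`. Attributes
#'   `global_overlap` (bands intersect at every age) and `bc_below_raw`
#'   (median ordering holds at every age).
#' @export
compare_growth_curves <- function(post_bc, post_raw, ages = 0:10,
                                  level = 0.95) {
  stopifnot(inherits(post_bc, "vb_posterior"),
            inherits(post_raw, "vb_posterior"))
  alpha <- (1 - level) / 2
  band <- function(post, t) {
    draws <- vb_length(rep(t, each = nrow(post$population)),
                       post$population$linf, post$population$k,
                       post$population$t0)
    m <- matrix(draws, nrow = nrow(post$population))
    apply(m, 2, quantile, probs = c(alpha, 0.5, 1 - alpha))
  }
  qb <- band(post_bc, ages)
  qr <- band(post_raw, ages)
  out <- tibble(
    age = ages,
    bc_lo = qb[1, ], bc_median = qb[2, ], bc_hi = qb[3, ],
    raw_lo = qr[1, ], raw_median = qr[2, ], raw_hi = qr[3, ],
    overlap = qb[1, ] <= qr[3, ] & qr[1, ] <= qb[3, ]
  )
  attr(out, "global_overlap") <- all(out$overlap)
  attr(out, "bc_below_raw") <- all(out$bc_median <= out$raw_median)
  out
}
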