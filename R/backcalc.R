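#' Predicted length at capture under the biological-intercept power law
#'
#' Evaluates `L_cpt = L0p - b * R0p^c + b * Rcpt^c`: total length at capture
#' as a power-law function of otolith radius at capture, anchored at the
#' species hatch length and the individual's hatch radius. This is the
#' regression mean fitted by [fit_proportionality()].
#'
#' @param length_0p Total length at hatching (mm).
#' @param radius_0p Otolith radius at hatching (mm, > 0).
#' @param radius_cpt Otolith radius at capture (mm, > 0).
#' @param b Proportionality coefficient (> 0).
#' @param c Proportionality exponent.
#' @return Predicted length at capture (mm). Vectorized over all arguments.
#' @export
predict_capture_length <- function(length_0p, radius_0p, radius_cpt, b, c) {
  if (any(radius_0p <= 0, na.rm = TRUE) || any(radius_cpt <= 0, na.rm = TRUE))
    abort("radii must be positive")
  length_0p - b * radius_0p^c + b * radius_cpt^c
}

#' Biological intercept of the back-calculation model
#'
#' Evaluates `a = L0p - b * R0p^c`, the per-individual intercept combining
#' the regression draws (b, c) with the individual's hatch radius (observed
#' or imputed). Always below `L0p` when `b > 0`.
#'
#' @inheritParams predict_capture_length
#' @return Intercept a (mm). Vectorized.
#' @export
biological_intercept_a <- function(length_0p, radius_0p, b, c) {
  if (any(radius_0p <= 0, na.rm = TRUE)) abort("radius_0p must be positive")
  length_0p - b * radius_0p^c
}

#' Modified Fry back-calculated length at age
#'
#' Log-linear interpolation of intercept-shifted length against log otolith
#' radius between the hatching anchor (`R0p`, `L0p`) and the capture anchor
#' (`Rcpt`, `Lcpt`):
#' `L_i = a + exp( ln(L0p - a) + [ln(Lcpt - a) - ln(L0p - a)] *
#'   [ln(R_i) - ln(R0p)] / [ln(Rcpt) - ln(R0p)] )`.
#' Returns exactly `L0p` at `R_i = R0p` and exactly `Lcpt` at `R_i = Rcpt`.
#'
#' Inputs violating the log-domain preconditions (`Lcpt <= a`, `L0p <= a`,
#' non-positive radii, `Rcpt = R0p`) yield `NA` rather than an error, so
#' that individual posterior draws can be skipped and counted.
#'
#' @param length_cpt Total length at capture (mm).
#' @param length_0p Total length at hatching (mm).
#' @param radius_cpt Otolith radius at capture (mm).
#' @param radius_0p Otolith radius at hatching (mm).
#' @param radius_i Otolith radius at the target age (mm).
#' @param a Biological intercept from [biological_intercept_a()] (mm).
#' @return Back-calculated length at age (mm), `NA` where not evaluable.
#'   Vectorized.
#' @export
modified_fry <- function(length_cpt, length_0p, radius_cpt, radius_0p,
                         radius_i, a) {
  n <- max(length(length_cpt), length(length_0p), length(radius_cpt),
           length(radius_0p), length(radius_i), length(a))
  length_cpt <- rep_len(length_cpt, n); length_0p <- rep_len(length_0p, n)
  radius_cpt <- rep_len(radius_cpt, n); radius_0p <- rep_len(radius_0p, n)
  radius_i <- rep_len(radius_i, n); a <- rep_len(a, n)
  ok <- !is.na(radius_i) & !is.na(radius_0p) & !is.na(a) &
    radius_i > 0 & radius_0p > 0 & radius_cpt > 0 &
    radius_cpt != radius_0p & length_cpt > a & length_0p > a
  out <- rep(NA_real_, n)
  frac <- (log(radius_i[ok]) - log(radius_0p[ok])) /
    (log(radius_cpt[ok]) - log(radius_0p[ok]))
  out[ok] <- a[ok] + exp(log(length_0p[ok] - a[ok]) +
    (log(length_cpt[ok] - a[ok]) - log(length_0p[ok] - a[ok])) * frac)
  # anchor identities exact in floating point
  at0 <- ok & radius_i == radius_0p
  atc <- ok & radius_i == radius_cpt
  out[at0] <- length_0p[at0]
  out[atc] <- length_cpt[atc]
  out
}

#' Priors for the length-radius proportionality fit
#'
#' Defaults follow the informative priors used for reef-fish otolith data:
#' `b ~ Normal(200, 200)` and `c ~ Normal(1, 1)`, both truncated below at
#' zero (the Modified Fry log-domain requires `a < L0p`, guaranteed only
#' for positive b). The residual scale has a half-Normal(0, 50 mm) prior.
#' The known hatch radii define the imputation population: missing hatch
#' radii are drawn from a truncated normal whose hyperparameters are
#' estimated jointly, with weakly-informative hyperpriors centred on the
#' observed hatch-radius mean.
#'
#' @param b_mean,b_sd Normal prior on b (mm per mm^c).
#' @param c_mean,c_sd Normal prior on c.
#' @param sigma_sd Half-normal prior scale on the residual sd (mm).
#' @param r0p_mu_sd Normal hyperprior sd (mm) on the hatch-radius
#'   population mean, centred on the mean of the known values.
#' @param r0p_sd_sd Half-normal hyperprior scale (mm) on the hatch-radius
#'   population sd.
#' @return A `prop_priors` list.
#' @export
prop_priors <- function(b_mean = 200, b_sd = 200, c_mean = 1, c_sd = 1,
                        sigma_sd = 50, r0p_mu_sd = 0.1, r0p_sd_sd = 0.1) {
  structure(list(b_mean = b_mean, b_sd = b_sd, c_mean = c_mean, c_sd = c_sd,
                 sigma_sd = sigma_sd, r0p_mu_sd = r0p_mu_sd,
                 r0p_sd_sd = r0p_sd_sd),
            class = "prop_priors")
}

PROP_MODEL <- "
model {
  b ~ dnorm(b_mean, pow(b_sd, -2)) T(0,)
  c ~ dnorm(c_mean, pow(c_sd, -2)) T(0,)
  sigma ~ dnorm(0, pow(sigma_sd, -2)) T(0,)
  mu_r0p ~ dnorm(r0p_center, pow(r0p_mu_sd, -2))
  sd_r0p ~ dnorm(0, pow(r0p_sd_sd, -2)) T(0,)
  tau <- pow(sigma, -2)
  tau_r <- pow(sd_r0p, -2)
  for (i in 1:N) {
    R0p[i] ~ dnorm(mu_r0p, tau_r) T(0,)
    mu[i] <- L0p - b * pow(R0p[i], c) + b * pow(Rcpt[i], c)
    Lcpt[i] ~ dnorm(mu[i], tau)
  }
}"

#' Fit the Bayesian length-radius proportionality model
#'
#' Fits `L_cpt ~ Normal(L0p - b * R0p^c + b * Rcpt^c, sigma)` over the
#' members of one back-calculation group. Missing hatch radii are included
#' as parameters: they share a truncated-normal population with the known
#' hatch radii, so each missing value acquires its own posterior updated by
#' the length-radius relationship. Non-convergent fits (any R-hat above the
#' threshold) are retried once with doubled iterations.
#'
#' @param members Tibble of group members (the `individuals` slot of a
#'   [growth_dataset()] restricted to one group): needs `individual_id`,
#'   `length_cpt`, `radius_cpt`, `radius_0p`, `length_0p` (single shared
#'   value); at least two `radius_0p` must be known.
#' @param priors A [prop_priors()].
#' @param settings An [mcmc_settings()].
#' @param group_key Label stored with the posterior.
#' @return A `proportionality_posterior`: list with `draws` (tibble of
#'   `b`, `c`, `sigma`, `mu_r0p`, `sd_r0p`, one row per retained draw),
#'   `imputed` (matrix of hatch-radius draws, one column per missing
#'   individual, named by `individual_id`), `r0p` (named vector of observed
#'   hatch radii, `NA` where missing), `n_draws`, `diagnostics` (R-hat and
#'   effective size per parameter), `converged`, and `group_key`.
#' @export
fit_proportionality <- function(members, priors = prop_priors(),
                                settings = mcmc_settings(),
                                group_key = "group") {
  members <- as_tibble(members)
  known <- !is.na(members$radius_0p)
  if (sum(known) < 2)
    abort(paste0(group_key, ": need at least 2 known hatch radii"))
  if (length(unique(members$length_0p)) != 1)
    abort(paste0(group_key, ": members must share one hatch length L0p"))
  if (sd(members$radius_cpt) == 0)
    abort(paste0(group_key, ": degenerate group, all capture radii equal"))

  data <- list(
    N = nrow(members),
    L0p = members$length_0p[1],
    Rcpt = members$radius_cpt,
    Lcpt = members$length_cpt,
    R0p = members$radius_0p,
    b_mean = priors$b_mean, b_sd = priors$b_sd,
    c_mean = priors$c_mean, c_sd = priors$c_sd,
    sigma_sd = priors$sigma_sd,
    r0p_center = mean(members$radius_0p[known]),
    r0p_mu_sd = priors$r0p_mu_sd, r0p_sd_sd = priors$r0p_sd_sd
  )
  miss_idx <- which(!known)
  monitor <- c("b", "c", "sigma", "mu_r0p", "sd_r0p",
               if (length(miss_idx) > 0) paste0("R0p[", miss_idx, "]"))
  inits <- function(ch) list(b = priors$b_mean, c = max(priors$c_mean, 0.5))

  fit_once <- function(s) {
    samples <- run_jags(PROP_MODEL, data, monitor, s, inits)
    diag <- mcmc_diagnostics(samples)
    list(samples = samples, diag = diag)
  }
  core <- c("b", "c", "sigma", "mu_r0p", "sd_r0p")
  fit <- fit_once(settings)
  bad <- any(fit$diag$rhat[fit$diag$parameter %in% core] >
               settings$rhat_threshold, na.rm = TRUE)
  if (bad) {
    retry <- settings
    retry$iter <- 2L * settings$iter
    retry$warmup <- 2L * settings$warmup
    fit <- fit_once(retry)
  }
  converged <- check_convergence(fit$diag, settings,
                                 paste0("fit_proportionality[", group_key, "]"),
                                 params = core)

  dm <- draws_matrix(fit$samples)
  imputed <- if (length(miss_idx) > 0) {
    dm[, paste0("R0p[", miss_idx, "]"), drop = FALSE]
  } else {
    matrix(numeric(0), nrow = nrow(dm), ncol = 0)
  }
  colnames(imputed) <- members$individual_id[miss_idx]
  structure(list(
    draws = as_tibble(dm[, core, drop = FALSE]),
    imputed = imputed,
    r0p = setNames(members$radius_0p, members$individual_id),
    n_draws = nrow(dm),
    diagnostics = fit$diag,
    converged = converged,
    group_key = group_key
  ), class = "proportionality_posterior")
}

#' @export
print.proportionality_posterior <- function(x, ...) {
  cat("<proportionality_posterior> group ", x$group_key, ": ", x$n_draws,
      " draws, ", ncol(x$imputed), " imputed hatch radii\n", sep = "")
  m <- colMeans(x$draws)
  cat(sprintf("  b = %.2f, c = %.3f, sigma = %.2f (posterior means)\n",
              m[["b"]], m[["c"]], m[["sigma"]]))
  invisible(x)
}

#' Degenerate posterior concentrated at fixed parameter values
#'
#' Builds a `proportionality_posterior` whose every draw equals the supplied
#' `(b, c)` and hatch radii. Used for noise-free oracle checks: pushing the
#' generative parameters through the back-calculation must reproduce the
#' simulated true lengths exactly.
#'
#' @param members Group members tibble (as in [fit_proportionality()]).
#' @param b,c Fixed parameter values.
#' @param r0p_values Named vector filling in any missing hatch radii.
#' @param n_draws Number of (identical) draws to emit.
#' @return A `proportionality_posterior`.
#' @export
point_mass_posterior <- function(members, b, c, r0p_values = NULL,
                                 n_draws = 1L) {
  members <- as_tibble(members)
  r0p <- setNames(members$radius_0p, members$individual_id)
  miss <- names(r0p)[is.na(r0p)]
  imputed <- matrix(numeric(0), nrow = n_draws, ncol = 0)
  if (length(miss) > 0) {
    if (is.null(r0p_values) || !all(miss %in% names(r0p_values)))
      abort("r0p_values must cover every missing hatch radius")
    imputed <- matrix(rep(r0p_values[miss], each = n_draws), nrow = n_draws,
                      dimnames = list(NULL, miss))
  }
  structure(list(
    draws = tibble(b = rep(b, n_draws), c = rep(c, n_draws),
                   sigma = rep(0, n_draws), mu_r0p = NA_real_,
                   sd_r0p = NA_real_),
    imputed = imputed,
    r0p = r0p,
    n_draws = n_draws,
    diagnostics = tibble(parameter = character(), rhat = numeric(),
                         ess = numeric()),
    converged = TRUE,
    group_key = "point_mass"
  ), class = "proportionality_posterior")
}

#' Back-calculate lengths-at-age for one group
#'
#' For every member, every age with a measured increment radius, and every
#' posterior draw: computes the biological intercept
#' `a = L0p - b * R0p^c` (using that draw's imputed hatch radius where the
#' measurement is missing) and evaluates the Modified Fry interpolation.
#' Reports the mean and standard deviation over evaluable draws — the
#' per-age size estimate with propagated regression and imputation
#' uncertainty.
#'
#' @param members Group members tibble.
#' @param increments Increment tibble covering the members.
#' @param posterior A `proportionality_posterior` for the group.
#' @param min_valid_frac Estimates based on fewer than this fraction of
#'   evaluable draws are flagged `unreliable`.
#' @return Tibble: `individual_id`, `age_i`, `length_mean`, `length_sd`,
#'   `n_valid_draws`, `unreliable`. Ages with missing radii yield `NA`
#'   estimates.
#' @export
backcalculate_group <- function(members, increments, posterior,
                                min_valid_frac = 0.5) {
  stopifnot(inherits(posterior, "proportionality_posterior"))
  members <- as_tibble(members)
  b <- posterior$draws$b
  cc <- posterior$draws$c
  n_draws <- posterior$n_draws
  out <- vector("list", nrow(members))
  for (i in seq_len(nrow(members))) {
    m <- members[i, ]
    inc <- increments[increments$individual_id == m$individual_id, ]
    inc <- inc[order(inc$age_i), ]
    if (nrow(inc) == 0) next
    r0p_draws <- if (!is.na(m$radius_0p)) {
      rep(m$radius_0p, n_draws)
    } else if (m$individual_id %in% colnames(posterior$imputed)) {
      posterior$imputed[, m$individual_id]
    } else {
      rep(NA_real_, n_draws)
    }
    a_draws <- biological_intercept_a(m$length_0p, r0p_draws, b, cc)
    res <- matrix(NA_real_, nrow = n_draws, ncol = nrow(inc))
    for (jj in seq_len(nrow(inc))) {
      if (is.na(inc$radius_i[jj])) next
      res[, jj] <- modified_fry(m$length_cpt, m$length_0p, m$radius_cpt,
                                r0p_draws, inc$radius_i[jj], a_draws)
    }
    n_valid <- colSums(!is.na(res))
    out[[i]] <- tibble(
      individual_id = m$individual_id,
      age_i = inc$age_i,
      length_mean = ifelse(n_valid > 0, colMeans(res, na.rm = TRUE),
                           NA_real_),
      length_sd = ifelse(n_valid > 1, apply(res, 2, sd, na.rm = TRUE),
                         ifelse(n_valid == 1, 0, NA_real_)),
      n_valid_draws = n_valid,
      unreliable = !is.na(inc$radius_i) & n_valid < min_valid_frac * n_draws
    )
  }
  dplyr::bind_rows(out)
}

#' Run the full back-calculation over a dataset
#'
#' Applies group selection ([select_backcalc_groups()]), fits the
#' proportionality model per eligible group ([fit_proportionality()]) and
#' back-calculates every member ([backcalculate_group()]), for species-level
#' groups, species-by-location groups, or both. Results annotate the
#' increment table: species-level estimates fill `li_sp_m` / `li_sp_sd`,
#' species-by-location estimates fill `li_sploc_m` / `li_sploc_sd`.
#' Individuals excluded by the eligibility rules keep `NA` estimates.
#'
#' @param ds A validated [growth_dataset()].
#' @param grouping `"species"`, `"species_by_location"`, or `"both"`.
#' @param priors A [prop_priors()].
#' @param settings An [mcmc_settings()]. Each group's fit derives its seed
#'   from `settings$seed` and the group index, so runs are reproducible.
#' @return List: `dataset` (annotated copy of `ds`), `report` (tibble of
#'   per-group status, exclusions and diagnostics), `posteriors` (named
#'   list of `proportionality_posterior` objects, names
#'   `<grouping>:<group_key>`), `estimates` (tibble of all per-age
#'   estimates with grouping labels).
#' @export
run_backcalculation <- function(ds, grouping = c("both", "species",
                                                 "species_by_location"),
                                priors = prop_priors(),
                                settings = mcmc_settings()) {
  stopifnot(inherits(ds, "growth_dataset"))
  grouping <- match.arg(grouping)
  modes <- if (grouping == "both") c("species", "species_by_location")
           else grouping
  annotated <- ds
  report <- list()
  posteriors <- list()
  estimates <- list()
  for (mode in modes) {
    target_m <- if (mode == "species") "li_sp_m" else "li_sploc_m"
    target_sd <- if (mode == "species") "li_sp_sd" else "li_sploc_sd"
    annotated$increments[[target_m]] <- NA_real_
    annotated$increments[[target_sd]] <- NA_real_
    groups <- select_backcalc_groups(ds, mode)
    for (gi in seq_len(nrow(groups))) {
      g <- groups[gi, ]
      excl <- g$exclusions[[1]]
      if (!g$eligible) {
        report[[length(report) + 1]] <- tibble(
          grouping = mode, group_key = g$group_key, status = "skipped",
          reason = "insufficient_r0p", n_members = 0L,
          n_excluded = nrow(excl), max_rhat = NA_real_)
        next
      }
      members <- ds$individuals[ds$individuals$individual_id %in%
                                  g$member_ids[[1]], ]
      gs <- settings
      gs$seed <- settings$seed + 1000L * match(mode, modes) + gi
      post <- tryCatch(
        fit_proportionality(members, priors, gs, group_key = g$group_key),
        error = function(e) e)
      if (inherits(post, "error")) {
        report[[length(report) + 1]] <- tibble(
          grouping = mode, group_key = g$group_key, status = "error",
          reason = conditionMessage(post), n_members = nrow(members),
          n_excluded = nrow(excl), max_rhat = NA_real_)
        next
      }
      est <- backcalculate_group(members, ds$increments, post)
      posteriors[[paste0(mode, ":", g$group_key)]] <- post
      estimates[[length(estimates) + 1]] <-
        dplyr::mutate(est, grouping = mode, group_key = g$group_key)
      idx <- match(paste(annotated$increments$individual_id,
                         annotated$increments$age_i),
                   paste(est$individual_id, est$age_i))
      hit <- !is.na(idx)
      annotated$increments[[target_m]][hit] <- est$length_mean[idx[hit]]
      annotated$increments[[target_sd]][hit] <- est$length_sd[idx[hit]]
      report[[length(report) + 1]] <- tibble(
        grouping = mode, group_key = g$group_key, status = "ok",
        reason = NA_character_, n_members = nrow(members),
        n_excluded = nrow(excl),
        max_rhat = max(post$diagnostics$rhat, na.rm = TRUE))
    }
  }
  list(dataset = annotated,
       report = dplyr::bind_rows(report),
       posteriors = posteriors,
       estimates = dplyr::bind_rows(estimates))
}
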