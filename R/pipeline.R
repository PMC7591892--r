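#' Pipeline configuration
#'
#' Assembles the stage toggles, priors, eligibility filters and MCMC
#' settings for [run_pipeline()]. Filter defaults encode the standard
#' eligibility rules: at least 2 known hatch radii per back-calculation
#' group, capture ages 0 and 1 excluded from back-calculation, hierarchical
#' growth fits on groups of at least 5 individuals with capture age above
#' 2 years, raw-data fits on groups larger than 10, and a 5% between-reader
#' CV threshold. Overrides are recorded in the run manifest.
#'
#' @param input Either a [simulation_config()] (the pipeline simulates its
#'   input) or a path to a long-format growth CSV.
#' @param grouping Back-calculation grouping passed to
#'   [run_backcalculation()].
#' @param stages Character vector of enabled stages, a subset of
#'   `c("validate", "qc", "backcalc", "growth", "compare")`. The input
#'   stage always runs; `growth` requires `backcalc`; `compare` requires
#'   `growth`.
#' @param prop_priors A [prop_priors()].
#' @param vb_priors A [vb_priors()] (applied to every group).
#' @param mcmc An [mcmc_settings()]; its seed drives every stochastic
#'   stage.
#' @param filters Named list overriding filter defaults
#'   (`min_known_r0p`, `min_individuals_hier`, `min_age_cpt_hier`,
#'   `min_individuals_raw`, `cv_threshold`).
#' @param read_pairs Optional tibble of double reads for the QC stage
#'   (`individual_id`, `age_reader1`, `age_reader2`).
#' @param out_dir Optional directory; when set, the annotated CSV and the
#'   JSON manifest are written there.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = simulation_config(),
                            grouping = "species",
                            stages = c("validate", "qc", "backcalc",
                                       "growth", "compare"),
                            prop_priors = otogrow::prop_priors(),
                            vb_priors = otogrow::vb_priors(),
                            mcmc = mcmc_settings(),
                            filters = list(),
                            read_pairs = NULL,
                            out_dir = NULL) {
  defaults <- list(min_known_r0p = 2, min_individuals_hier = 5,
                   min_age_cpt_hier = 2, min_individuals_raw = 10,
                   cv_threshold = 5)
  unknown <- setdiff(names(filters), names(defaults))
  if (length(unknown) > 0)
    abort(paste0("unknown filter option(s): ", paste(unknown, collapse = ", ")))
  filt <- utils::modifyList(defaults, filters)
  stages <- match.arg(stages, c("validate", "qc", "backcalc", "growth",
                                "compare"), several.ok = TRUE)
  structure(list(input = input, grouping = grouping, stages = stages,
                 prop_priors = prop_priors, vb_priors = vb_priors,
                 mcmc = mcmc, filters = filt,
                 filter_overrides = names(filters),
                 read_pairs = read_pairs, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full growth-analysis pipeline
#'
#' Orchestrates simulate/read, validate, ageing QC, back-calculation,
#' hierarchical and raw growth fits, and curve comparison, under one seed.
#' A stage failure for one group halts downstream stages for that group
#' only; the manifest is returned (and written) even on partial failure,
#' and identical configuration and seed give identical manifest content.
#'
#' @param cfg A [pipeline_config()].
#' @return A run manifest list: `seed`, `stages_run`, `input` (source and
#'   counts), `validation` (violation count and report), `qc` (flagged
#'   ids), `backcalc` (per-group report), `growth` (per-group fit
#'   summaries), `compare` (per-group overlap results), `exclusions`
#'   (ledger accounting for every individual), `status` (`"ok"` if all
#'   enabled stages succeeded for all groups), plus `results` (the heavy
#'   objects: annotated dataset, posteriors), which is dropped from the
#'   JSON manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  manifest <- list(
    otogrow_version = as.character(packageVersion("otogrow")),
    seed = cfg$mcmc$seed,
    stages_run = character(),
    filter_overrides = cfg$filter_overrides,
    status = "ok"
  )
  results <- list()

  # --- input stage
  if (inherits(cfg$input, "simulation_config")) {
    sim <- simulate_dataset(cfg$input)
    ds <- sim$dataset
    results$truth <- sim$truth
    manifest$input <- list(source = "simulated", seed = cfg$input$seed)
  } else {
    ds <- read_growth_csv(cfg$input)
    manifest$input <- list(source = cfg$input)
  }
  counts <- summarise_dataset_counts(ds)
  manifest$input$n_individuals <- counts$n_individuals
  manifest$input$n_species <- counts$n_species
  manifest$input$n_increment_rows <- counts$n_increment_rows
  results$dataset <- ds

  # --- validation
  if ("validate" %in% cfg$stages) {
    report <- validate_dataset(ds)
    manifest$stages_run <- c(manifest$stages_run, "validate")
    manifest$validation <- list(n_violations = nrow(report),
                                violations = as.data.frame(report))
    if (nrow(report) > 0) manifest$status <- "validation_failed"
  }

  # --- ageing QC
  if ("qc" %in% cfg$stages) {
    manifest$stages_run <- c(manifest$stages_run, "qc")
    if (!is.null(cfg$read_pairs)) {
      flags <- flag_rereads(cfg$read_pairs, cfg$filters$cv_threshold)
      manifest$qc <- list(n_pairs = nrow(cfg$read_pairs),
                          n_flagged = nrow(flags),
                          flagged = flags$individual_id)
    } else {
      manifest$qc <- list(n_pairs = 0L, n_flagged = 0L,
                          note = "no double reads supplied")
    }
  }

  # --- back-calculation
  bc <- NULL
  if ("backcalc" %in% cfg$stages && manifest$status == "ok") {
    bc <- run_backcalculation(ds, cfg$grouping, cfg$prop_priors, cfg$mcmc)
    manifest$stages_run <- c(manifest$stages_run, "backcalc")
    manifest$backcalc <- list(report = as.data.frame(bc$report))
    if (any(bc$report$status == "error")) manifest$status <- "partial"
    results$backcalc <- bc
    # exclusion ledger: members + exclusions = group size for every group
    groups <- select_backcalc_groups(ds, if (cfg$grouping == "both")
      "species" else cfg$grouping)
    ledger <- lapply(seq_len(nrow(groups)), function(i) {
      g <- groups[i, ]
      tibble(group_key = g$group_key,
             n_members = g$n_members,
             n_excluded = nrow(g$exclusions[[1]]),
             n_total = g$n_members + nrow(g$exclusions[[1]]))
    })
    manifest$exclusions <- as.data.frame(dplyr::bind_rows(ledger))
  }

  # --- growth fits + comparison
  if ("growth" %in% cfg$stages && !is.null(bc) &&
        manifest$status %in% c("ok", "partial")) {
    manifest$stages_run <- c(manifest$stages_run, "growth")
    growth_summaries <- list()
    compare_summaries <- list()
    results$growth <- list()
    mode <- if (cfg$grouping == "both") "species" else cfg$grouping
    est_all <- bc$estimates[bc$estimates$grouping == mode, ]
    for (gk in unique(est_all$group_key)) {
      est <- est_all[est_all$group_key == gk, ]
      members <- ds$individuals[ds$individuals$individual_id %in%
                                  est$individual_id, ]
      fit_data <- filter_for_hierarchical_fit(
        est, ds$individuals, cfg$filters$min_individuals_hier,
        cfg$filters$min_age_cpt_hier)
      if (nrow(fit_data) == 0) {
        growth_summaries[[gk]] <- list(group_key = gk, status = "skipped",
                                       reason = "insufficient_individuals")
        next
      }
      gset <- cfg$mcmc
      gset$seed <- cfg$mcmc$seed + 5000L + match(gk, unique(est_all$group_key))
      res <- tryCatch(
        convergence_protocol(fit_data, cfg$vb_priors, gset),
        error = function(e) e)
      if (inherits(res, "error")) {
        growth_summaries[[gk]] <- list(group_key = gk, status = "error",
                                       reason = conditionMessage(res))
        manifest$status <- "partial"
        next
      }
      post <- res$posterior
      results$growth[[gk]] <- list(hierarchical = post,
                                   action_log = res$action_log)
      growth_summaries[[gk]] <- list(
        group_key = gk, status = "ok",
        n_individuals = post$meta$n_individuals,
        n_obs = post$meta$n_obs,
        dropped = post$meta$dropped,
        posterior_mean = as.list(round(colMeans(
          post$population[c("linf", "k", "t0")]), 4)))

      if ("compare" %in% cfg$stages) {
        grp_ind <- ds$individuals[ds$individuals$individual_id %in%
                                    post$meta$individuals, ]
        if (nrow(grp_ind) > cfg$filters$min_individuals_raw) {
          raw_post <- tryCatch(
            fit_vb_raw(grp_ind, cfg$vb_priors, gset),
            error = function(e) e)
          if (!inherits(raw_post, "error")) {
            ages <- 0:max(grp_ind$age_cpt)
            cmp <- compare_growth_curves(post, raw_post, ages)
            results$growth[[gk]]$raw <- raw_post
            results$growth[[gk]]$comparison <- cmp
            compare_summaries[[gk]] <- list(
              group_key = gk,
              global_overlap = attr(cmp, "global_overlap"),
              bc_below_raw = attr(cmp, "bc_below_raw"))
          }
        } else {
          compare_summaries[[gk]] <- list(group_key = gk,
                                          skipped = "n_raw_too_small")
        }
      }
    }
    manifest$growth <- unname(growth_summaries)
    if ("compare" %in% cfg$stages) {
      manifest$stages_run <- c(manifest$stages_run, "compare")
      manifest$compare <- unname(compare_summaries)
    }
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(bc))
      write_growth_csv(bc$dataset, file.path(cfg$out_dir, "annotated.csv"))
    jsonlite::write_json(manifest,
                         file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  manifest$results <- results
  invisible(manifest)
}
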