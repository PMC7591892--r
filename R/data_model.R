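#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif rbinom sd quantile setNames update complete.cases
#' @importFrom utils packageVersion head
NULL

# Table-2 schema: deposited column name -> internal name.
SCHEMA_COLS <- c(
  Family = "family", Genus = "genus", Species = "species", ID = "individual_id",
  Age_i = "age_i", R_i = "radius_i",
  Age_cpt = "age_cpt", R_cpt = "radius_cpt", L_cpt = "length_cpt",
  L_0p = "length_0p", R_0p = "radius_0p",
  Li_sp_m = "li_sp_m", Li_sp_sd = "li_sp_sd",
  Li_sploc_m = "li_sploc_m", Li_sploc_sd = "li_sploc_sd",
  Weight = "weight", Location = "location", Observer = "observer"
)

NUMERIC_COLS <- c("Age_i", "R_i", "Age_cpt", "R_cpt", "L_cpt", "L_0p", "R_0p",
                  "Li_sp_m", "Li_sp_sd", "Li_sploc_m", "Li_sploc_sd", "Weight")
CAPTURE_COLS <- c("family", "genus", "species", "location", "age_cpt",
                  "radius_cpt", "length_cpt", "length_0p", "radius_0p",
                  "weight", "observer")

#' Construct a growth dataset
#'
#' A `growth_dataset` holds one row per individual fish at capture together
#' with its otolith increment reads in long format (one row per individual
#' and integer age). This is the in-memory form of the 18-column long-format
#' CSV schema used for otolith increment datasets.
#'
#' @param individuals Tibble with one row per fish: `individual_id`, `family`,
#'   `genus`, `species`, `location`, `age_cpt` (years), `radius_cpt` (mm),
#'   `length_cpt` (mm, total length), `length_0p` (mm, species-level length at
#'   hatching), `radius_0p` (mm, otolith radius at hatching, may be `NA`),
#'   `weight` (g, optional), `observer` (optional).
#' @param increments Tibble with one row per increment read: `individual_id`,
#'   `age_i` (integer years), `radius_i` (mm, may be `NA`). Back-calculation
#'   output columns `li_sp_m`, `li_sp_sd`, `li_sploc_m`, `li_sploc_sd` are
#'   carried when present (as reference annotations, never as model input).
#' @param provenance Free-text source/version string.
#' @return An object of class `growth_dataset`.
#' @export
growth_dataset <- function(individuals, increments, provenance = "in-memory") {
  individuals <- as_tibble(individuals)
  increments <- as_tibble(increments)
  for (col in c("li_sp_m", "li_sp_sd", "li_sploc_m", "li_sploc_sd")) {
    if (!col %in% names(increments)) increments[[col]] <- NA_real_
  }
  for (col in c("weight", "observer")) {
    if (!col %in% names(individuals)) {
      individuals[[col]] <- if (col == "weight") NA_real_ else NA_character_
    }
  }
  structure(
    list(individuals = individuals, increments = increments,
         provenance = provenance),
    class = "growth_dataset"
  )
}

#' @export
print.growth_dataset <- function(x, ...) {
  cat("<growth_dataset> ", nrow(x$individuals), " individuals, ",
      nrow(x$increments), " increment reads, ",
      dplyr::n_distinct(x$individuals$species), " species\n", sep = "")
  cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' Read a long-format otolith growth CSV
#'
#' Reads the 18-column long-format schema (`Family`, `Genus`, `Species`, `ID`,
#' `Age_i`, `R_i`, `Age_cpt`, `R_cpt`, `L_cpt`, `L_0p`, `R_0p`, `Li_sp_m`,
#' `Li_sp_sd`, `Li_sploc_m`, `Li_sploc_sd`, `Weight`, `Location`, `Observer`)
#' with `NA` as the sole missing-value token, and splits it into one
#' individual-at-capture record per unique `ID` plus one increment record per
#' row. Column-name matching is exact and case-sensitive. Pre-computed
#' `Li_*` columns, when present, are retained as reference annotations only.
#'
#' @param path Path to the CSV file.
#' @return A [growth_dataset()].
#' @export
read_growth_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = "NA", progress = FALSE
  )
  missing_cols <- setdiff(names(SCHEMA_COLS), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("schema error: missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  raw <- raw[names(SCHEMA_COLS)]
  # parse numeric columns, reporting the first offending row
  for (col in NUMERIC_COLS) {
    vals <- raw[[col]]
    parsed <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & is.na(parsed))
    if (length(bad) > 0) {
      abort(paste0("parse error: non-numeric value ", dQuote(vals[bad[1]]),
                   " in column ", col, ", row ", bad[1]))
    }
    raw[[col]] <- parsed
  }
  names(raw) <- unname(SCHEMA_COLS[names(raw)])

  # capture-level fields must be constant within each ID
  cap <- dplyr::distinct(raw, dplyr::across(dplyr::all_of(
    c("individual_id", CAPTURE_COLS))))
  dup <- cap$individual_id[duplicated(cap$individual_id)]
  if (length(dup) > 0) {
    abort(paste0("integrity error: inconsistent capture-level values for ID(s): ",
                 paste(sort(unique(dup)), collapse = ", ")))
  }
  increments <- raw[c("individual_id", "age_i", "radius_i",
                      "li_sp_m", "li_sp_sd", "li_sploc_m", "li_sploc_sd")]
  growth_dataset(cap, increments, provenance = path)
}

#' Write a growth dataset to the long-format CSV schema
#'
#' Emits the 18 columns in schema order, long format (one row per individual
#' and age), `NA` for missing values. Inverse of [read_growth_csv()] up to
#' numeric formatting.
#'
#' @param ds A [growth_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_growth_csv <- function(ds, path) {
  stopifnot(inherits(ds, "growth_dataset"))
  long <- dplyr::left_join(ds$increments, ds$individuals, by = "individual_id")
  long <- long[unname(SCHEMA_COLS)]
  names(long) <- names(SCHEMA_COLS)
  readr::write_csv(long, path, na = "NA", progress = FALSE)
  invisible(path)
}

new_violation <- function(individual_id, rule, detail) {
  tibble(individual_id = as.character(individual_id), rule = rule,
         detail = detail)
}

#' Validate a growth dataset against its schema invariants
#'
#' Checks every structural invariant of the dataset: increment IDs resolve to
#' an individual, no duplicate (individual, age) pairs, ages within `[0,
#' age_cpt]`, radii positive, non-decreasing with age and bounded by the
#' capture radius, hatch length below capture length for fish of age >= 1,
#' and agreement between the hatch radius `radius_0p` and the age-0 increment
#' radius. Violations are returned as data, never raised.
#'
#' @param ds A [growth_dataset()].
#' @return A tibble of violations (`individual_id`, `rule`, `detail`),
#'   ordered by individual then rule; zero rows when the dataset is valid.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "growth_dataset"))
  ind <- ds$individuals
  inc <- ds$increments
  out <- list()

  unresolved <- setdiff(inc$individual_id, ind$individual_id)
  if (length(unresolved) > 0) {
    out <- c(out, list(new_violation(unresolved, "id_resolution",
      "increment rows reference an ID absent from the individual records")))
  }
  if (anyDuplicated(ind$individual_id) > 0) {
    dup <- unique(ind$individual_id[duplicated(ind$individual_id)])
    out <- c(out, list(new_violation(dup, "id_unique",
      "multiple capture records for one ID")))
  }
  key <- paste(inc$individual_id, inc$age_i)
  if (anyDuplicated(key) > 0) {
    dup <- unique(inc$individual_id[duplicated(key)])
    out <- c(out, list(new_violation(dup, "age_duplicate",
      "duplicate (individual, age) increment rows")))
  }

  j <- dplyr::left_join(inc, ind[c("individual_id", "age_cpt", "radius_cpt",
                                   "radius_0p")], by = "individual_id")
  bad_age <- j$individual_id[!is.na(j$age_cpt) &
                               (j$age_i < 0 | j$age_i > j$age_cpt)]
  if (length(bad_age) > 0) {
    out <- c(out, list(new_violation(unique(bad_age), "age_range",
      "age_i outside [0, age_cpt]")))
  }
  bad_pos <- j$individual_id[!is.na(j$radius_i) & j$radius_i <= 0]
  if (length(bad_pos) > 0) {
    out <- c(out, list(new_violation(unique(bad_pos), "radius_positive",
      "non-positive increment radius")))
  }
  tol <- 1e-9
  bad_cap <- j$individual_id[!is.na(j$radius_i) & !is.na(j$radius_cpt) &
                               j$radius_i > j$radius_cpt * (1 + tol)]
  if (length(bad_cap) > 0) {
    out <- c(out, list(new_violation(unique(bad_cap), "radius_le_rcpt",
      "increment radius exceeds radius at capture")))
  }

  mono <- j |>
    dplyr::filter(!is.na(.data$radius_i)) |>
    dplyr::arrange(.data$individual_id, .data$age_i) |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(ok = all(diff(.data$radius_i) >= -tol), .groups = "drop")
  if (any(!mono$ok)) {
    out <- c(out, list(new_violation(mono$individual_id[!mono$ok],
      "radius_monotone", "increment radii decrease with age")))
  }

  bad_l0 <- ind$individual_id[!is.na(ind$age_cpt) & ind$age_cpt >= 1 &
                                ind$length_0p >= ind$length_cpt]
  if (length(bad_l0) > 0) {
    out <- c(out, list(new_violation(bad_l0, "l0p_below_lcpt",
      "hatch length not below capture length for age >= 1")))
  }

  age0 <- j[j$age_i == 0 & !is.na(j$radius_i) & !is.na(j$radius_0p), ]
  bad_r0 <- age0$individual_id[abs(age0$radius_i - age0$radius_0p) >
                                 tol * pmax(1, age0$radius_0p)]
  if (length(bad_r0) > 0) {
    out <- c(out, list(new_violation(unique(bad_r0), "r0p_consistency",
      "radius_0p differs from the age-0 increment radius")))
  }

  report <- if (length(out) == 0) {
    new_violation(character(), character(), character())
  } else {
    dplyr::bind_rows(out)
  }
  dplyr::arrange(report, .data$individual_id, .data$rule)
}

#' Summarise dataset composition
#'
#' Counts of individuals, species, families and locations, plus increment
#' totals — the headline figures one reports for an otolith increment
#' collection.
#'
#' @param ds A [growth_dataset()].
#' @return A one-row tibble of counts.
#' @export
summarise_dataset_counts <- function(ds) {
  stopifnot(inherits(ds, "growth_dataset"))
  tibble(
    n_individuals = nrow(ds$individuals),
    n_species = dplyr::n_distinct(paste(ds$individuals$genus,
                                        ds$individuals$species)),
    n_families = dplyr::n_distinct(ds$individuals$family),
    n_locations = dplyr::n_distinct(ds$individuals$location),
    n_increment_rows = nrow(ds$increments),
    n_known_r0p = sum(!is.na(ds$individuals$radius_0p))
  )
}

group_key_cols <- function(grouping) {
  switch(grouping,
    species = c("genus", "species"),
    species_by_location = c("genus", "species", "location"),
    abort(paste0("unknown grouping: ", dQuote(grouping),
                 " (use \"species\" or \"species_by_location\")"))
  )
}

#' Select eligible back-calculation groups
#'
#' Partitions individuals into fitting groups (by species, or by species and
#' location) and applies the eligibility rules for the Bayesian
#' length-radius fit: individuals aged exactly one year at capture are
#' excluded (a single increment carries no trajectory information), age-0
#' individuals likewise (back-calculation interpolates between hatching and
#' capture), and a group is retained only if at least two of its remaining
#' members have a measured hatch radius `radius_0p` — with a single known
#' hatch radius the radius population, and hence the imputation prior for
#' missing values, is unidentifiable.
#'
#' @param ds A [growth_dataset()].
#' @param grouping `"species"` or `"species_by_location"`.
#' @return A tibble with one row per group: the grouping columns, a
#'   `group_key` string, `eligible` flag, list-columns `member_ids` and
#'   `exclusions` (tibble of `individual_id`, `reason`), and counts
#'   `n_members`, `n_known_r0p`. Every individual of a group appears in
#'   exactly one of `member_ids` / `exclusions`.
#' @export
select_backcalc_groups <- function(ds, grouping = "species") {
  stopifnot(inherits(ds, "growth_dataset"))
  keys <- group_key_cols(grouping)
  ind <- ds$individuals
  if (nrow(ind) == 0) {
    return(tibble(group_key = character(), eligible = logical(),
                  member_ids = list(), exclusions = list(),
                  n_members = integer(), n_known_r0p = integer()))
  }
  ind$group_key <- do.call(paste, c(ind[keys], sep = "|"))

  grp <- split(ind, ind$group_key)
  rows <- lapply(grp, function(g) {
    excl_age1 <- g$individual_id[g$age_cpt == 1]
    excl_age0 <- g$individual_id[g$age_cpt == 0]
    members <- g[!(g$individual_id %in% c(excl_age1, excl_age0)), ]
    n_known <- sum(!is.na(members$radius_0p))
    eligible <- n_known >= 2
    exclusions <- dplyr::bind_rows(
      new_exclusion(excl_age0, "age_at_capture_zero"),
      new_exclusion(excl_age1, "age_at_capture_one"),
      if (!eligible) new_exclusion(members$individual_id, "insufficient_r0p")
    )
    ids <- if (eligible) sort(members$individual_id) else character()
    tibble(
      group_key = g$group_key[1],
      !!!setNames(as.list(g[1, keys]), keys),
      eligible = eligible,
      member_ids = list(ids),
      exclusions = list(dplyr::arrange(exclusions, .data$individual_id)),
      n_members = length(ids),
      n_known_r0p = n_known
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$group_key)
}

new_exclusion <- function(ids, reason) {
  tibble(individual_id = sort(as.character(ids)),
         reason = rep(reason, length(ids)))
}
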