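#' Between-reader ageing coefficient of variation
#'
#' Ageing precision between two independent otolith readers:
#' `CV = 100 * s / m`, with `m` the mean of the two age reads and `s` their
#' sample standard deviation (divisor R - 1 = 1, so
#' `s = |a1 - a2| / sqrt(2)`). Symmetric in the two reads and
#' scale-invariant.
#'
#' @param age_reader1,age_reader2 Age reads (years, >= 0). Vectorized.
#' @return CV in percent; `NA` where both reads are zero (undefined mean).
#' @export
reader_cv <- function(age_reader1, age_reader2) {
  if (any(age_reader1 < 0, na.rm = TRUE) || any(age_reader2 < 0,
                                                na.rm = TRUE))
    abort("age reads must be non-negative")
  m <- (age_reader1 + age_reader2) / 2
  s <- abs(age_reader1 - age_reader2) / sqrt(2)
  ifelse(m > 0, 100 * s / m, NA_real_)
}

#' Flag otoliths needing a common re-read
#'
#' Individuals whose between-reader CV strictly exceeds the threshold are
#' flagged for a joint reading session; a CV exactly at the threshold is
#' not flagged. Pairs with undefined CV (both reads zero) are flagged, as
#' they cannot be certified precise.
#'
#' @param pairs Tibble with `individual_id`, `age_reader1`, `age_reader2`.
#' @param threshold CV threshold in percent (default 5).
#' @return Tibble of flagged rows (`individual_id`, `cv`), ordered by
#'   `individual_id`.
#' @export
flag_rereads <- function(pairs, threshold = 5) {
  stopifnot(threshold > 0)
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0)
    return(tibble(individual_id = character(), cv = numeric()))
  cv <- reader_cv(pairs$age_reader1, pairs$age_reader2)
  flagged <- is.na(cv) | cv > threshold
  out <- tibble(individual_id = as.character(pairs$individual_id[flagged]),
                cv = cv[flagged])
  dplyr::arrange(out, .data$individual_id)
}
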