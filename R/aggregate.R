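# Person-nutrient accounting: stratum prevalences x population counts,
# prevented-vs-baseline bookkeeping, nutrient and global summaries.
# Counts stay real-valued end to end; rounding happens only in rendered
# reports, never in the accounting.

#' People with inadequate (or excess) intake in a stratum
#'
#' @param prev Prevalence in [0, 1] (may be `NA` for "not assessed").
#' @param persons Stratum population count, >= 0.
#' @return Real-valued person count (no premature rounding).
#' @export
count_inadequate <- function(prev, persons) {
  if (any(!is.na(prev) & (prev < 0 | prev > 1))) {
    rlang::abort("prevalence must lie in [0, 1]")
  }
  if (any(persons < 0)) rlang::abort("population counts must be >= 0")
  prev * persons
}

#' Total person-nutrient inadequacies for one scenario
#'
#' Sums `n_inadequate` over every (country, age-sex group, nutrient)
#' stratum, so one person inadequate in k nutrients counts k times.
#'
#' @param results Adequacy tibble for a single scenario with columns
#'   `country`, `age_sex_group`, `nutrient`, `n_inadequate`.
#' @return Total person-nutrient inadequacies (persons).
#' @export
person_nutrient_total <- function(results) {
  if (nrow(results) == 0) return(0)
  check_columns(results, c("country", "age_sex_group", "nutrient",
                           "n_inadequate"), "adequacy results")
  key <- paste(results$country, results$age_sex_group, results$nutrient)
  if (anyDuplicated(key)) {
    rlang::abort("duplicate (country, age_sex_group, nutrient) rows in adequacy results")
  }
  sum(results$n_inadequate)
}

#' Inadequacies prevented by a scenario
#'
#' `baseline - scenario`, where both totals are computed over the same
#' universe of strata.  A negative value (a scenario that lowers levels)
#' is reported as-is, never clamped.
#'
#' @param baseline_total Person-nutrient total under no fortification.
#' @param scenario_total Person-nutrient total under the scenario.
#' @export
prevented <- function(baseline_total, scenario_total) {
  baseline_total - scenario_total
}

#' Attach population counts to stratum prevalences
#'
#' @param adequacy Tibble with `country`, `age_sex_group`, `nutrient`,
#'   `prev_inadequate`, `prev_excess`.
#' @param populations Tibble `country`, `age_sex_group`, `persons`.
#' @return `adequacy` with `persons`, `n_inadequate`, `n_excess` columns.
#'   Strata missing from the population table raise an integrity error so
#'   prevented-counts can never be biased by coverage mismatch.
#' @export
add_person_counts <- function(adequacy, populations) {
  check_columns(populations, c("country", "age_sex_group", "persons"),
                "population")
  out <- dplyr::left_join(adequacy, populations,
                          by = c("country", "age_sex_group"))
  if (anyNA(out$persons)) {
    miss <- unique(paste(out$country[is.na(out$persons)],
                         out$age_sex_group[is.na(out$persons)]))
    rlang::abort(paste0("strata missing from the population table: ",
                        paste(utils::head(miss, 5), collapse = "; ")))
  }
  dplyr::mutate(out,
    n_inadequate = count_inadequate(.data$prev_inadequate, .data$persons),
    n_excess = count_inadequate(.data$prev_excess, .data$persons))
}

#' Nutrient-level totals for one scenario
#'
#' @param results Adequacy tibble with person counts (one scenario).
#' @return Tibble `nutrient`, `n_inadequate`, `n_excess` (`n_excess` is
#'   `NA` for nutrients without a harmonised UL).
#' @export
nutrient_totals <- function(results) {
  results |>
    dplyr::group_by(.data$nutrient) |>
    dplyr::summarise(
      n_inadequate = sum(.data$n_inadequate),
      n_excess = if (all(is.na(.data$n_excess))) NA_real_
                 else sum(.data$n_excess, na.rm = TRUE),
      .groups = "drop")
}

#' Country-level population-weighted prevalence
#'
#' Used both for reporting and as the need signal in the expansion rule.
#'
#' @param results Adequacy tibble with person counts (one scenario).
#' @return Tibble `country`, `nutrient`, `prevalence`.
#' @export
country_prevalence <- function(results) {
  results |>
    dplyr::group_by(.data$country, .data$nutrient) |>
    dplyr::summarise(
      prevalence = sum(.data$n_inadequate) / sum(.data$persons),
      .groups = "drop")
}
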