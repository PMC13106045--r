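# Fortification programmes and the six policy scenarios.
#
# A programme row is one country x vehicle with GFDx-style indicators:
# status (mandatory/voluntary/none), population-level per-capita vehicle
# intake F (g/day), fraction industrially processed IP, fraction fortified
# in compliance with the standard FC, and a standard mapping nutrient ->
# (level mg/kg, compound).  The per-stratum intake contribution is
#
#   I_mcsa = sum over vehicles of F_csa * IP * FC * D / 1000
#
# with F_csa the age-sex-scaled vehicle intake in g/day and D the standard
# level in mg/kg, giving mg/day before conversion to the registry unit.

#' Impute missing programme indicators
#'
#' Fills missing industrially-processed (IP) and compliance (FC) fractions
#' with the median of observed values for the same vehicle within the
#' country's region, falling back to the global vehicle median.  Imputed
#' values are flagged (`ip_imputed`, `fc_imputed`), a provenance used by the
#' compliance sensitivity analysis.
#'
#' @param programs Programme tibble with columns `country`, `vehicle`,
#'   `status`, `percap_intake`, `industrially_processed`, `compliance`
#'   (`NA` = missing).
#' @param regions Tibble mapping `country` to `region`.
#' @return The programme tibble with no missing IP/FC and flag columns.
#' @export
impute_missing <- function(programs, regions) {
  check_columns(programs, c("country", "vehicle", "industrially_processed",
                            "compliance"), "programme")
  check_columns(regions, c("country", "region"), "region")
  p <- dplyr::left_join(programs, regions, by = "country")
  if (anyNA(p$region)) {
    rlang::abort(paste0("countries missing from the region map: ",
                        paste(unique(p$country[is.na(p$region)]), collapse = ", ")))
  }
  impute_col <- function(p, col, flag) {
    x <- p[[col]]
    obs <- !is.na(x)
    no_obs <- setdiff(unique(p$vehicle), unique(p$vehicle[obs]))
    if (length(no_obs) > 0) {
      rlang::abort(paste0("no observed ", col, " value anywhere for vehicle(s): ",
                          paste(no_obs, collapse = ", ")))
    }
    regional <- stats::aggregate(x[obs],
                                 list(vehicle = p$vehicle[obs], region = p$region[obs]),
                                 stats::median)
    global <- stats::aggregate(x[obs], list(vehicle = p$vehicle[obs]), stats::median)
    for (i in which(!obs)) {
      m <- regional$x[regional$vehicle == p$vehicle[i] & regional$region == p$region[i]]
      if (length(m) == 0) m <- global$x[global$vehicle == p$vehicle[i]]
      x[i] <- m
    }
    p[[col]] <- x
    # idempotent: re-running leaves earlier provenance flags in place
    p[[flag]] <- !obs | (if (flag %in% names(p)) p[[flag]] else FALSE)
    p
  }
  p <- impute_col(p, "industrially_processed", "ip_imputed")
  p <- impute_col(p, "compliance", "fc_imputed")
  dplyr::select(p, -"region")
}

#' Age-sex-specific vehicle intake
#'
#' Scales the population-level per-capita vehicle intake to age-sex groups
#' using caloric-intake ratios (group caloric intake over the country's
#' population-mean caloric intake).  A country missing from the scaling
#' table falls back to ratio 1 with a warning, so the population-weighted
#' group mean equals the population-level figure by construction.
#'
#' @param programs Programme tibble (see [impute_missing()]).
#' @param scaling Tibble with `age_sex_group`, `calorie_ratio` and
#'   optionally `country` (omit for a single global set of ratios).
#' @return Tibble `country`, `vehicle`, `age_sex_group`, `intake_g_day`.
#' @export
scale_vehicle_intake <- function(programs, scaling) {
  check_columns(scaling, c("age_sex_group", "calorie_ratio"), "calorie scaling")
  per_country <- "country" %in% names(scaling)
  if (per_country) {
    missing <- setdiff(unique(programs$country), unique(scaling$country))
    if (length(missing) > 0) {
      rlang::warn(paste0("no calorie scaling for ", paste(missing, collapse = ", "),
                         "; falling back to ratio 1"))
      fallback <- tidyr::expand_grid(country = missing,
                                     age_sex_group = unique(scaling$age_sex_group),
                                     calorie_ratio = 1)
      scaling <- dplyr::bind_rows(scaling[c("country", "age_sex_group", "calorie_ratio")],
                                  fallback)
    }
    out <- dplyr::inner_join(programs[c("country", "vehicle", "percap_intake")],
                             scaling[c("country", "age_sex_group", "calorie_ratio")],
                             by = "country", relationship = "many-to-many")
  } else {
    out <- tidyr::expand_grid(
      programs[c("country", "vehicle", "percap_intake")],
      scaling[c("age_sex_group", "calorie_ratio")]
    )
  }
  dplyr::transmute(out,
    country = .data$country, vehicle = .data$vehicle,
    age_sex_group = .data$age_sex_group,
    intake_g_day = .data$percap_intake * .data$calorie_ratio)
}

#' Fortificant intake contribution per stratum
#'
#' Evaluates the contribution equation: for each country, age-sex group and
#' nutrient, the sum over the five vehicles of
#' `F_csa (g/day) x IP x FC x D (mg/kg) / 1000`, converted from mg/day to
#' the nutrient's registry unit.  Programmes with status `none`, or vehicles
#' whose standard omits the nutrient, contribute zero.  Vehicles are summed
#' in canonical order so repeated evaluation is bit-reproducible.
#'
#' @param programs Imputed programme tibble.
#' @param standards Tibble `country`, `vehicle`, `nutrient`,
#'   `level_mg_per_kg`, `compound` for current standards.
#' @param scaling Calorie-scaling tibble (see [scale_vehicle_intake()]).
#' @param units Nutrient units registry, [nutrient_units()] by default.
#' @return Tibble `country`, `age_sex_group`, `nutrient`, `contribution`
#'   (registry units/day); strata without any contributing vehicle are
#'   absent (treat as zero).
#' @export
fortificant_contribution <- function(programs, standards, scaling,
                                     units = nutrient_units()) {
  check_columns(standards, c("country", "vehicle", "nutrient",
                             "level_mg_per_kg"), "standards")
  unknown <- setdiff(unique(standards$nutrient), units$nutrient)
  if (length(unknown) > 0) {
    rlang::abort(paste0("nutrient(s) missing from the units registry: ",
                        paste(unknown, collapse = ", ")))
  }
  active <- dplyr::filter(programs, .data$status != "none")
  if (nrow(active) == 0) {
    return(tibble::tibble(country = character(), age_sex_group = character(),
                          nutrient = character(), contribution = numeric()))
  }
  f <- scale_vehicle_intake(active, scaling)
  per_vehicle <- active |>
    dplyr::inner_join(standards, by = c("country", "vehicle")) |>
    dplyr::inner_join(f, by = c("country", "vehicle"),
                      relationship = "many-to-many") |>
    dplyr::left_join(units[c("nutrient", "to_unit")], by = "nutrient") |>
    dplyr::mutate(term = .data$intake_g_day * .data$industrially_processed *
                    .data$compliance * .data$level_mg_per_kg / 1000 *
                    .data$to_unit)
  per_vehicle |>
    dplyr::mutate(vehicle = factor(.data$vehicle, levels = VEHICLES)) |>
    dplyr::arrange(.data$country, .data$age_sex_group, .data$nutrient,
                   .data$vehicle) |>
    dplyr::group_by(.data$country, .data$age_sex_group, .data$nutrient) |>
    dplyr::summarise(contribution = sum(.data$term), .groups = "drop")
}

#' Default expansion-eligibility thresholds
#'
#' A country qualifies for a new programme on a vehicle when baseline
#' (no-fortification) inadequacy is high and the vehicle is widely eaten
#' and industrially processed.  Intake thresholds are vehicle-specific
#' because condiment-like vehicles (salt, oil) are consumed in grams, not
#' hundreds of grams.
#'
#' @param min_baseline_prevalence Minimum country-level baseline prevalence
#'   of inadequacy for at least one nutrient the vehicle can deliver.
#' @param min_vehicle_intake Named vector of minimum per-capita intake
#'   (g/day) per vehicle.
#' @param min_processed_fraction Minimum industrially-processed fraction.
#' @export
expansion_params <- function(min_baseline_prevalence = 0.2,
                             min_vehicle_intake = c(wheat_flour = 50,
                                                    maize_flour = 50,
                                                    oil = 10, rice = 50,
                                                    salt = 5),
                             min_processed_fraction = 0.5) {
  list(min_baseline_prevalence = min_baseline_prevalence,
       min_vehicle_intake = min_vehicle_intake,
       min_processed_fraction = min_processed_fraction)
}

#' Expansion eligibility rule
#'
#' @param baseline_prevalence Country-level prevalence of inadequate intake
#'   under no fortification (for the candidate nutrient).
#' @param percap_intake Per-capita vehicle intake, g/day.
#' @param industrially_processed Industrially processed fraction.
#' @param vehicle Vehicle label (selects the intake threshold).
#' @param params Thresholds from [expansion_params()].
#' @return Logical; vectorised over all arguments.
#' @export
expansion_eligible <- function(baseline_prevalence, percap_intake,
                               industrially_processed, vehicle,
                               params = expansion_params()) {
  baseline_prevalence >= params$min_baseline_prevalence &
    percap_intake >= unname(params$min_vehicle_intake[vehicle]) &
    industrially_processed >= params$min_processed_fraction
}

#' Declarative scenario specification
#'
#' Returns the rule set for one of the six canonical scenarios:
#' `no_fortification` (all compliance zeroed), `current` (identity),
#' `improved_compliance` (compliance floored at 90% for every programme,
#' mandatory and voluntary alike), `aligned_standards` (standards aligned
#' to international guidelines), `aligned_improved` (both), and
#' `aligned_improved_expanded` (both, plus new mandatory programmes where
#' the expansion rule holds).
#'
#' @param name One of [scenario_names()].
#' @param compliance_floor Compliance floor applied where the scenario
#'   improves compliance (default 0.9).
#' @param align_rule `"max_with_guideline"` (default; alignment never
#'   lowers an existing level), `"replace_with_guideline"`, or `"keep"`.
#' @param expansion Thresholds from [expansion_params()].
#' @export
scenario_spec <- function(name, compliance_floor = 0.9,
                          align_rule = c("max_with_guideline",
                                         "replace_with_guideline", "keep"),
                          expansion = expansion_params()) {
  check_scenario(name)
  align_rule <- match.arg(align_rule)
  list(
    name = name,
    zero_compliance = name == "no_fortification",
    compliance_floor = if (name %in% c("improved_compliance", "aligned_improved",
                                       "aligned_improved_expanded"))
      compliance_floor else NA_real_,
    align_rule = if (name %in% c("aligned_standards", "aligned_improved",
                                 "aligned_improved_expanded"))
      align_rule else "keep",
    expand = name == "aligned_improved_expanded",
    expansion = expansion
  )
}

# align one vehicle's standards to guidelines; never lowers a level under
# the max rule and adds guideline nutrients absent from the current standard
align_standards <- function(standards, guidelines, programs, rule) {
  if (rule == "keep") return(standards)
  check_columns(guidelines, c("vehicle", "nutrient", "level_mg_per_kg",
                              "compound"), "guideline standards")
  active <- dplyr::filter(programs, .data$status != "none")
  target <- dplyr::inner_join(active[c("country", "vehicle")],
                              guidelines, by = "vehicle",
                              relationship = "many-to-many")
  if (rule == "replace_with_guideline") return(target)
  merged <- dplyr::full_join(
    dplyr::semi_join(standards, active, by = c("country", "vehicle")),
    target, by = c("country", "vehicle", "nutrient"),
    suffix = c("_cur", "_gl"))
  dplyr::transmute(merged,
    country = .data$country, vehicle = .data$vehicle, nutrient = .data$nutrient,
    level_mg_per_kg = pmax(dplyr::coalesce(.data$level_mg_per_kg_cur, 0),
                           dplyr::coalesce(.data$level_mg_per_kg_gl, 0)),
    compound = dplyr::if_else(
      dplyr::coalesce(.data$level_mg_per_kg_gl, 0) >
        dplyr::coalesce(.data$level_mg_per_kg_cur, 0),
      .data$compound_gl, .data$compound_cur,
      missing = dplyr::coalesce(.data$compound_cur, .data$compound_gl)))
}

#' Transform programmes and standards into a scenario
#'
#' @param programs Imputed programme tibble.
#' @param standards Current-standards tibble.
#' @param guidelines Guideline-standards tibble (`vehicle`, `nutrient`,
#'   `level_mg_per_kg`, `compound`); required when the scenario aligns
#'   standards or expands coverage.
#' @param spec A [scenario_spec()].
#' @param baseline_prev Country-level baseline prevalence tibble
#'   (`country`, `nutrient`, `prevalence`) under no fortification; required
#'   when `spec$expand` is `TRUE`.
#' @return A list with transformed `programs` (gains a logical `added`
#'   column marking programmes created by expansion) and `standards`.
#' @export
apply_scenario <- function(programs, standards, guidelines = NULL, spec,
                           baseline_prev = NULL) {
  p <- programs
  if (!"added" %in% names(p)) p$added <- FALSE
  s <- standards
  if (spec$align_rule != "keep" || spec$expand) {
    if (is.null(guidelines)) {
      rlang::abort(paste0("scenario '", spec$name, "' requires guideline standards"))
    }
  }
  if (spec$zero_compliance) {
    p$compliance <- 0
    return(list(programs = p, standards = s))
  }
  s <- align_standards(s, guidelines, p, spec$align_rule)
  if (spec$expand) {
    if (is.null(baseline_prev)) {
      rlang::abort("expansion requires baseline (no-fortification) prevalence")
    }
    check_columns(baseline_prev, c("country", "nutrient", "prevalence"),
                  "baseline prevalence")
    candidates <- dplyr::filter(p, .data$status == "none")
    if (nrow(candidates) > 0) {
      need <- candidates |>
        dplyr::inner_join(guidelines[c("vehicle", "nutrient")], by = "vehicle",
                          relationship = "many-to-many") |>
        dplyr::inner_join(baseline_prev, by = c("country", "nutrient")) |>
        dplyr::group_by(.data$country, .data$vehicle) |>
        dplyr::summarise(max_prev = max(.data$prevalence), .groups = "drop")
      candidates <- dplyr::left_join(candidates, need,
                                     by = c("country", "vehicle")) |>
        dplyr::filter(expansion_eligible(
          dplyr::coalesce(.data$max_prev, 0), .data$percap_intake,
          .data$industrially_processed, .data$vehicle, spec$expansion)) |>
        dplyr::select(-"max_prev")
      if (nrow(candidates) > 0) {
        new_key <- candidates[c("country", "vehicle")]
        p <- dplyr::rows_update(
          p,
          dplyr::mutate(new_key, status = "mandatory",
                        compliance = spec$compliance_floor, added = TRUE),
          by = c("country", "vehicle"))
        new_std <- dplyr::inner_join(new_key, guidelines, by = "vehicle",
                                     relationship = "many-to-many")
        s <- dplyr::bind_rows(s, new_std)
      }
    }
  }
  if (!is.na(spec$compliance_floor)) {
    live <- p$status != "none"
    p$compliance[live] <- pmax(p$compliance[live], spec$compliance_floor)
  }
  list(programs = p, standards = s)
}
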