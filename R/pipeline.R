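# Orchestration: impute programmes once, compute the no-fortification
# baseline once, then for each scenario transform programmes/standards,
# evaluate the contribution equation, shift the intake distributions,
# re-evaluate adequacy and UL exceedance, aggregate person counts, and
# cost the programmes.  Everything downstream of the generated inputs is
# deterministic.

# adequacy for one set of intake rows (already shifted); reuses baseline
# prevalences for strata whose contribution is zero
compute_adequacy <- function(intake, requirements, uls, populations,
                             baseline = NULL) {
  rows <- intake |>
    dplyr::left_join(requirements, by = c("nutrient", "age_sex_group")) |>
    dplyr::left_join(uls, by = c("nutrient", "age_sex_group"))
  if (anyNA(rows$ar)) {
    miss <- rows[is.na(rows$ar), c("nutrient", "age_sex_group")]
    rlang::abort(paste0("no requirement for: ",
                        paste(utils::head(unique(paste(miss$nutrient,
                                                       miss$age_sex_group)), 5),
                              collapse = "; ")))
  }
  need <- rep(TRUE, nrow(rows))
  out_prev <- numeric(nrow(rows))
  if (!is.null(baseline)) {
    base <- baseline[c("country", "age_sex_group", "nutrient",
                       "prev_inadequate")]
    names(base)[4] <- ".base_prev"
    rows <- dplyr::left_join(rows, base,
                             by = c("country", "age_sex_group", "nutrient"))
    need <- rows$contribution > 0 | is.na(rows$.base_prev)
    out_prev[!need] <- rows$.base_prev[!need]
  }
  if (any(need)) {
    out_prev[need] <- prev_inadequate(
      rows$family[need], rows$mean[need], rows$cv[need], rows$ar[need],
      rows$req_cv[need], rows$req_family[need],
      label = paste(rows$country[need], rows$age_sex_group[need],
                    rows$nutrient[need]))
  }
  rows$prev_inadequate <- out_prev
  rows$prev_excess <- prev_excess(rows$family, rows$mean, rows$cv, rows$ul)
  rows |>
    dplyr::select("country", "age_sex_group", "nutrient",
                  "prev_inadequate", "prev_excess") |>
    add_person_counts(populations)
}

#' Run the six-scenario fortification pipeline
#'
#' For each requested scenario this computes stratum-level adequacy
#' (prevalence and person counts of inadequate and excess intake),
#' nutrient-level and global person-nutrient totals, inadequacies
#' prevented relative to no fortification and to current fortification,
#' UL-exceedance summaries, and the premix/industry/government cost
#' breakdown with vehicle shares.  Optionally writes tidy CSV outputs and
#' a YAML run manifest.
#'
#' @param world A world list from [generate_world()] or [read_world()].
#' @param scenarios Scenario names to run (default all six).
#' @param shift_convention `"cv"` (default) or `"sd"`: what "the same
#'   amount of variability" preserves when the distribution is shifted.
#' @param align_rule Standards-alignment rule (see [scenario_spec()]).
#' @param expansion Expansion thresholds from [expansion_params()].
#' @param out_dir Optional directory for CSV outputs and the manifest.
#' @return A list: `adequacy` (stratum rows, all scenarios),
#'   `nutrient_summary`, `global_summary`, `country_prevalence`,
#'   `cost_breakdown`, `cost_summary`, `manifest`.
#' @export
run_scenarios <- function(world, scenarios = scenario_names(),
                          shift_convention = c("cv", "sd"),
                          align_rule = c("max_with_guideline",
                                         "replace_with_guideline", "keep"),
                          expansion = expansion_params(),
                          out_dir = NULL) {
  shift_convention <- match.arg(shift_convention)
  align_rule <- match.arg(align_rule)
  check_scenario(scenarios)

  programs <- impute_missing(world$programs, world$regions)
  baseline <- compute_adequacy(world$intake, world$requirements, world$uls,
                               world$populations)
  baseline_country <- country_prevalence(baseline)

  adequacy <- list(); nutrient_summary <- list()
  cost_breakdown <- list(); cost_rows <- list(); ppv <- list()

  for (sc in scenarios) {
    spec <- scenario_spec(sc, align_rule = align_rule, expansion = expansion)
    tr <- apply_scenario(programs, world$standards, world$guidelines, spec,
                         baseline_prev = baseline_country)
    contrib <- fortificant_contribution(tr$programs, tr$standards,
                                        world$calorie_scaling)
    shifted <- world$intake |>
      dplyr::left_join(contrib, by = c("country", "age_sex_group", "nutrient")) |>
      dplyr::mutate(contribution = dplyr::coalesce(.data$contribution, 0))
    sh <- shift_dist(shifted$family, shifted$mean, shifted$cv,
                     shifted$contribution, convention = shift_convention)
    shifted$mean <- sh$mean; shifted$cv <- sh$cv
    adq <- compute_adequacy(shifted, world$requirements, world$uls,
                            world$populations, baseline = baseline)
    adq <- dplyr::left_join(
      adq, shifted[c("country", "age_sex_group", "nutrient", "contribution")],
      by = c("country", "age_sex_group", "nutrient"))
    adequacy[[sc]] <- dplyr::mutate(adq, scenario = sc, .before = 1)
    nutrient_summary[[sc]] <- dplyr::mutate(nutrient_totals(adq),
                                            scenario = sc, .before = 1)
    costs <- scenario_costs(tr$programs, tr$standards, world$compounds,
                            world$supply, world$facilities,
                            world$populations, world$cost_params)
    cost_breakdown[[sc]] <- dplyr::mutate(costs$breakdown, scenario = sc,
                                          .before = 1)
    cost_rows[[sc]] <- costs$summary
    ppv[[sc]] <- dplyr::mutate(costs$summary$by_vehicle, scenario = sc,
                               .before = 1)
  }

  adequacy <- dplyr::bind_rows(adequacy)
  nutrient_summary <- dplyr::bind_rows(nutrient_summary)
  baseline_total <- person_nutrient_total(baseline)
  totals <- vapply(scenarios, function(sc) {
    person_nutrient_total(adequacy[adequacy$scenario == sc,
                                   c("country", "age_sex_group", "nutrient",
                                     "n_inadequate")])
  }, numeric(1))
  current_total <- if ("current" %in% scenarios) totals[["current"]] else NA_real_
  global_summary <- tibble::tibble(
    scenario = scenarios,
    n_inadequate = unname(totals),
    prevented_vs_baseline = prevented(baseline_total, unname(totals)),
    prevented_vs_current = if (is.na(current_total)) NA_real_
      else prevented(current_total, unname(totals)),
    n_excess = vapply(cost_rows, function(cr) NA_real_, numeric(1)),
    cost_total = vapply(cost_rows, function(cr) cr$total, numeric(1),
                        USE.NAMES = FALSE),
    cost_premix = vapply(cost_rows, function(cr) cr$premix, numeric(1),
                         USE.NAMES = FALSE),
    cost_industry = vapply(cost_rows, function(cr) cr$industry, numeric(1),
                           USE.NAMES = FALSE),
    cost_government = vapply(cost_rows, function(cr) cr$government,
                             numeric(1), USE.NAMES = FALSE),
    per_person_mean = vapply(cost_rows, function(cr) cr$per_person_mean,
                             numeric(1), USE.NAMES = FALSE),
    per_person_sd = vapply(cost_rows, function(cr) cr$per_person_sd,
                           numeric(1), USE.NAMES = FALSE))
  global_summary$n_excess <- vapply(scenarios, function(sc) {
    sum(adequacy$n_excess[adequacy$scenario == sc], na.rm = TRUE)
  }, numeric(1), USE.NAMES = FALSE)

  result <- list(
    adequacy = adequacy,
    nutrient_summary = nutrient_summary,
    global_summary = global_summary,
    country_prevalence = baseline_country,
    cost_breakdown = dplyr::bind_rows(cost_breakdown),
    cost_summary = dplyr::bind_rows(ppv),
    manifest = list(
      settings = list(scenarios = scenarios,
                      shift_convention = shift_convention,
                      align_rule = align_rule,
                      expansion = lapply(expansion, as.list),
                      seed = world$config$seed),
      baseline_person_nutrient_total = baseline_total,
      global_totals = stats::setNames(as.list(unname(totals)), scenarios),
      input_checksums = table_checksums(world)))

  if (!is.null(out_dir)) write_run_outputs(result, out_dir)
  result
}

# md5 of each input table's CSV serialisation, for the run manifest
table_checksums <- function(world) {
  tabs <- Filter(is.data.frame, world)
  out <- lapply(names(tabs), function(nm) {
    f <- tempfile(fileext = ".csv")
    on.exit(unlink(f))
    utils::write.csv(tabs[[nm]], f, row.names = FALSE)
    unname(tools::md5sum(f))
  })
  stats::setNames(out, names(tabs))
}

write_run_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$adequacy, file.path(out_dir, "adequacy.csv"))
  readr::write_csv(result$nutrient_summary,
                   file.path(out_dir, "nutrient_summary.csv"))
  readr::write_csv(result$global_summary,
                   file.path(out_dir, "global_summary.csv"))
  readr::write_csv(result$country_prevalence,
                   file.path(out_dir, "country_baseline_prevalence.csv"))
  readr::write_csv(result$cost_breakdown,
                   file.path(out_dir, "cost_breakdown.csv"))
  readr::write_csv(result$cost_summary, file.path(out_dir, "cost_summary.csv"))
  yaml::write_yaml(result$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
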