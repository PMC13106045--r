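# The three sensitivity analyses: calcium-in-wheat alignment, alternative
# compliance estimates, and compound-price scaling.  Each re-runs the
# relevant part of the pipeline and reports paired deltas; nothing is
# re-estimated, so deltas isolate the single toggled input.

#' Sensitivity to aligning calcium standards in wheat flour
#'
#' Calcium fortification of wheat flour is a major cost driver but is
#' seldom practised, so alignment with guidelines adds it almost
#' everywhere.  This runs the alignment scenarios with the calcium row of
#' the wheat-flour guideline present (ON) and removed (OFF) and reports
#' the deltas in person-nutrient inadequacies and costs.
#'
#' @param world A world list.
#' @param scenarios Scenarios to compare (defaults to the three aligned
#'   scenarios).
#' @param ... Passed to [run_scenarios()].
#' @return A list with `on`, `off` (global summaries) and `delta`
#'   (ON minus OFF, per scenario).
#' @export
sensitivity_calcium <- function(world,
                                scenarios = c("aligned_standards",
                                              "aligned_improved",
                                              "aligned_improved_expanded"),
                                ...) {
  world_off <- world
  world_off$guidelines <- dplyr::filter(
    world$guidelines,
    !(.data$vehicle == "wheat_flour" & .data$nutrient == "calcium"))
  on <- run_scenarios(world, scenarios = scenarios, ...)$global_summary
  off <- run_scenarios(world_off, scenarios = scenarios, ...)$global_summary
  delta <- dplyr::tibble(
    scenario = on$scenario,
    d_n_inadequate = on$n_inadequate - off$n_inadequate,
    d_cost_total = on$cost_total - off$cost_total,
    d_cost_premix = on$cost_premix - off$cost_premix)
  list(on = on, off = off, delta = delta)
}

#' Sensitivity to alternative compliance estimates
#'
#' Observed compliance rests on uncertain proxies; this re-runs adequacy
#' and costs with an alternative compliance table covering the same
#' country x vehicle universe and reports deltas against the original.
#'
#' @param world A world list.
#' @param alt_compliance Tibble `country`, `vehicle`, `compliance` with
#'   exactly the original programme universe.
#' @param scenarios Scenarios to compare (default all six).
#' @param ... Passed to [run_scenarios()].
#' @return A list with `original`, `alternative` (global summaries) and
#'   `delta` (alternative minus original).
#' @export
sensitivity_compliance <- function(world, alt_compliance,
                                   scenarios = scenario_names(), ...) {
  check_columns(alt_compliance, c("country", "vehicle", "compliance"),
                "alternative compliance")
  key_w <- paste(world$programs$country, world$programs$vehicle)
  key_a <- paste(alt_compliance$country, alt_compliance$vehicle)
  if (!setequal(key_w, key_a) || length(key_a) != length(unique(key_a))) {
    rlang::abort("alternative compliance table must cover exactly the programme universe")
  }
  world_alt <- world
  world_alt$programs <- world$programs |>
    dplyr::select(-"compliance") |>
    dplyr::left_join(alt_compliance, by = c("country", "vehicle"))
  original <- run_scenarios(world, scenarios = scenarios, ...)$global_summary
  alternative <- run_scenarios(world_alt, scenarios = scenarios, ...)$global_summary
  delta <- dplyr::tibble(
    scenario = original$scenario,
    d_n_inadequate = alternative$n_inadequate - original$n_inadequate,
    d_cost_total = alternative$cost_total - original$cost_total)
  list(original = original, alternative = alternative, delta = delta)
}

#' Sensitivity of costs to compound prices
#'
#' Scales every compound price by each factor and recomputes scenario
#' costs.  Because premix cost is linear in prices and the markups are
#' fixed multipliers, the premix component scales exactly by the factor
#' and the relative change in total cost equals
#' `(factor - 1) x premix share of total`.
#'
#' @param world A world list.
#' @param factors Positive price multipliers (default `c(0.5, 1.5)`,
#'   i.e. prices varied down and up by 50%).
#' @param scenario Scenario whose costs are scaled (default `"current"`).
#' @param ... Passed to [run_scenarios()].
#' @return Tibble with one row per factor: premix and total cost, and the
#'   relative total-cost change against factor 1.
#' @export
sensitivity_price <- function(world, factors = c(0.5, 1.5),
                              scenario = "current", ...) {
  if (any(factors <= 0)) rlang::abort("price factors must be > 0")
  run_at <- function(k) {
    w <- world
    w$compounds <- dplyr::mutate(w$compounds,
                                 price_usd_per_kg = .data$price_usd_per_kg * k)
    run_scenarios(w, scenarios = scenario, ...)$global_summary
  }
  ref <- run_at(1)
  rows <- lapply(factors, function(k) {
    g <- run_at(k)
    tibble::tibble(factor = k, cost_premix = g$cost_premix,
                   cost_total = g$cost_total,
                   rel_total_change = g$cost_total / ref$cost_total - 1)
  })
  dplyr::bind_rows(
    tibble::tibble(factor = 1, cost_premix = ref$cost_premix,
                   cost_total = ref$cost_total, rel_total_change = 0),
    dplyr::bind_rows(rows))
}
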