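# Bottom-up annual programme costs (2021 USD/yr): premix + industry +
# government per country x vehicle, with capital costs annualised as an
# annuity and premix adjusted for shipping, taxes/duties and domestic
# logistics markups applied multiplicatively in supply-chain order.

#' Default cost parameters
#'
#' All values are configurable inputs, never hard-coded results: discount
#' rate and lifespans drive the annuity, markups adjust premix, and the
#' unit costs price one facility's (industry) or one programme's
#' (government) recurrent and capital items in 2021 USD.
#'
#' @return A nested list matching the structure of the cost-parameters
#'   YAML file.
#' @export
default_cost_parameters <- function() {
  list(
    discount_rate = 0.03,
    equipment_life_yr = 10,
    planning_life_yr = 10,
    markups = list(shipping = 0.10, taxes_duties = 0.05,
                   domestic_logistics = 0.08),
    industry_unit_costs = list(
      fortification_equipment = 75000, qaqc_equipment = 20000,
      qaqc_supplies = 5000, labour = 15000, training = 3000,
      management_overhead = 10000),
    government_unit_costs = list(
      monitoring_equipment = 50000, monitoring_supplies = 10000,
      monitoring_labour = 40000, social_marketing = 30000,
      training = 10000, management_overhead = 20000,
      planning_launch = 200000)
  )
}

merge_cost_parameters <- function(params) {
  utils::modifyList(default_cost_parameters(), params)
}

#' Annualise a capital cost
#'
#' Converts a one-time capital outlay into the equivalent constant annual
#' cost via the annuity formula `capital * r / (1 - (1 + r)^-life)`; at a
#' zero discount rate this reduces to straight-line `capital / life`.
#'
#' @param capital Capital cost (USD).
#' @param life Useful life in years, > 0.
#' @param rate Annual discount rate, >= 0.
#' @return USD per year; vectorised.
#' @export
annualise <- function(capital, life, rate) {
  if (any(life <= 0)) rlang::abort("equipment life must be > 0 years")
  if (any(rate < 0)) rlang::abort("discount rate must be >= 0")
  ifelse(rate == 0, capital / life,
         capital * rate / (1 - (1 + rate)^(-life)))
}

#' Premix cost per tonne of food vehicle
#'
#' For each nutrient in the standard, the level in mg/kg equals g of
#' nutrient per tonne of vehicle; dividing by the compound's activity
#' (elemental fraction) and by 1000 gives kg of compound per tonne, priced
#' at the compound's USD/kg.  The base cost is then marked up
#' multiplicatively for international shipping, taxes and duties, and
#' domestic transport/storage/handling, in that order.
#'
#' @param standard Tibble `nutrient`, `level_mg_per_kg`, `compound` for one
#'   country x vehicle standard (zero rows = unfortified, costs $0/tonne).
#' @param compounds Tibble `compound`, `nutrient`, `activity`,
#'   `price_usd_per_kg`.
#' @param markups List with `shipping`, `taxes_duties`,
#'   `domestic_logistics` fractions.
#' @return USD per tonne of fortified vehicle.
#' @export
premix_cost_per_tonne <- function(standard, compounds,
                                  markups = default_cost_parameters()$markups) {
  if (nrow(standard) == 0) return(0)
  check_columns(compounds, c("compound", "nutrient", "activity",
                             "price_usd_per_kg"), "compounds")
  if (any(compounds$activity <= 0 | compounds$activity > 1)) {
    rlang::abort("compound activity must lie in (0, 1]")
  }
  m <- dplyr::left_join(standard, compounds, by = c("compound", "nutrient"))
  if (anyNA(m$activity)) {
    rlang::abort(paste0("no compound specification for nutrient(s): ",
                        paste(unique(m$nutrient[is.na(m$activity)]), collapse = ", ")))
  }
  base <- sum(m$level_mg_per_kg / m$activity / 1000 * m$price_usd_per_kg)
  base * (1 + markups$shipping) * (1 + markups$taxes_duties) *
    (1 + markups$domestic_logistics)
}

#' Annual quantity of fortified food vehicle
#'
#' @param supply_tonnes Annual vehicle supply in the food system, tonnes/yr.
#' @param ip Industrially processed fraction in [0, 1].
#' @param fc Compliance fraction in [0, 1].
#' @return Tonnes of fortified vehicle per year; vectorised.
#' @export
fortified_tonnage <- function(supply_tonnes, ip, fc) {
  if (any(ip < 0 | ip > 1 | fc < 0 | fc > 1)) {
    rlang::abort("IP and FC fractions must lie in [0, 1]")
  }
  supply_tonnes * ip * fc
}

#' Annual industry-related cost for one country x vehicle programme
#'
#' Per facility: annualised fortification and QA-QC equipment, plus
#' recurrent QA-QC supplies, labour, training, and management/overhead/
#' administration; multiplied by the facility count.
#'
#' @param facilities Number of industrial processing facilities, >= 0.
#' @param params Cost-parameter list (see [default_cost_parameters()]).
#' @return USD per year; vectorised over `facilities`.
#' @export
industry_cost <- function(facilities, params = default_cost_parameters()) {
  if (any(facilities < 0)) rlang::abort("facility count must be >= 0")
  u <- params$industry_unit_costs
  per_facility <-
    annualise(u$fortification_equipment, params$equipment_life_yr,
              params$discount_rate) +
    annualise(u$qaqc_equipment, params$equipment_life_yr,
              params$discount_rate) +
    u$qaqc_supplies + u$labour + u$training + u$management_overhead
  facilities * per_facility
}

#' Annual government-related cost for one country x vehicle programme
#'
#' Annualised monitoring equipment plus recurrent monitoring supplies,
#' monitoring labour (industry, import and commercial monitoring), social
#' marketing, training, and management/overhead/administration.  New
#' programmes additionally carry annualised planning and launch costs.
#'
#' @param is_new `TRUE` for programmes created by the expansion scenario.
#' @param params Cost-parameter list.
#' @return USD per year; vectorised over `is_new`.
#' @export
government_cost <- function(is_new, params = default_cost_parameters()) {
  u <- params$government_unit_costs
  base <- annualise(u$monitoring_equipment, params$equipment_life_yr,
                    params$discount_rate) +
    u$monitoring_supplies + u$monitoring_labour + u$social_marketing +
    u$training + u$management_overhead
  base + ifelse(is_new,
                annualise(u$planning_launch, params$planning_life_yr,
                          params$discount_rate), 0)
}

#' Cost breakdown and global summary for one scenario
#'
#' A programme is costed when it is active in the scenario: status is not
#' `none`, compliance is positive, and its standard carries at least one
#' nutrient (so the no-fortification scenario costs $0).  Premix cost is
#' per-tonne cost x fortified tonnage; industry and government costs
#' follow [industry_cost()] and [government_cost()].  Per-person costs
#' divide country totals by country population; the summary's mean and SD
#' of per-person cost are taken across the five vehicle-level global
#' figures.
#'
#' @param programs Scenario-transformed programme tibble (with `added`).
#' @param standards Scenario-transformed standards tibble.
#' @param compounds Compound-specification tibble.
#' @param supply Tibble `country`, `vehicle`, `supply_tonnes`.
#' @param facilities Tibble `country`, `vehicle`, `facilities`.
#' @param populations Population tibble (`country`, `age_sex_group`,
#'   `persons`).
#' @param params Cost-parameter list (partial lists are completed with
#'   defaults).
#' @return A list with `breakdown` (country x vehicle premix/industry/
#'   government/total/per_person) and `summary` (global total, vehicle
#'   totals and percentage shares, per-person mean and SD across
#'   vehicles).
#' @export
scenario_costs <- function(programs, standards, compounds, supply,
                           facilities, populations,
                           params = default_cost_parameters()) {
  params <- merge_cost_parameters(params)
  check_columns(supply, c("country", "vehicle", "supply_tonnes"), "supply")
  check_columns(facilities, c("country", "vehicle", "facilities"), "facilities")
  if (!"added" %in% names(programs)) programs$added <- FALSE
  country_pop <- populations |>
    dplyr::group_by(.data$country) |>
    dplyr::summarise(population = sum(.data$persons), .groups = "drop")

  fortified <- standards |>
    dplyr::group_by(.data$country, .data$vehicle) |>
    dplyr::summarise(n_nutrients = dplyr::n(), .groups = "drop")
  active <- programs |>
    dplyr::inner_join(fortified, by = c("country", "vehicle")) |>
    dplyr::filter(.data$status != "none", .data$compliance > 0,
                  .data$n_nutrients > 0)

  if (nrow(active) == 0) {
    breakdown <- tibble::tibble(
      country = character(), vehicle = character(), premix = numeric(),
      industry = numeric(), government = numeric(), total = numeric(),
      per_person = numeric())
  } else {
    per_tonne <- active |>
      dplyr::select("country", "vehicle") |>
      dplyr::mutate(premix_per_tonne = purrr::map2_dbl(
        .data$country, .data$vehicle, function(co, ve) {
          std <- standards[standards$country == co & standards$vehicle == ve, ]
          premix_cost_per_tonne(std, compounds, params$markups)
        }))
    breakdown <- active |>
      dplyr::left_join(per_tonne, by = c("country", "vehicle")) |>
      dplyr::left_join(supply, by = c("country", "vehicle")) |>
      dplyr::left_join(facilities, by = c("country", "vehicle")) |>
      dplyr::left_join(country_pop, by = "country")
    if (anyNA(breakdown$supply_tonnes) || anyNA(breakdown$facilities)) {
      rlang::abort("active programme lacks a supply or facility record")
    }
    if (anyNA(breakdown$population) || any(breakdown$population <= 0)) {
      rlang::abort("active programme in a country with zero or missing population")
    }
    breakdown <- breakdown |>
      dplyr::mutate(
        premix = .data$premix_per_tonne *
          fortified_tonnage(.data$supply_tonnes, .data$industrially_processed,
                            .data$compliance),
        industry = industry_cost(.data$facilities, params),
        government = government_cost(.data$added, params),
        total = .data$premix + .data$industry + .data$government,
        per_person = .data$total / .data$population) |>
      dplyr::select("country", "vehicle", "premix", "industry",
                    "government", "total", "per_person")
  }

  global_pop <- sum(country_pop$population)
  by_vehicle <- tibble::tibble(vehicle = VEHICLES) |>
    dplyr::left_join(
      breakdown |>
        dplyr::group_by(.data$vehicle) |>
        dplyr::summarise(total = sum(.data$total), .groups = "drop"),
      by = "vehicle") |>
    dplyr::mutate(total = dplyr::coalesce(.data$total, 0),
                  per_person = .data$total / global_pop)
  grand_total <- sum(by_vehicle$total)
  by_vehicle$share_pct <- if (grand_total > 0)
    100 * by_vehicle$total / grand_total else rep(0, nrow(by_vehicle))

  list(
    breakdown = breakdown,
    summary = list(
      total = grand_total,
      premix = sum(breakdown$premix),
      industry = sum(breakdown$industry),
      government = sum(breakdown$government),
      by_vehicle = by_vehicle,
      per_person_mean = mean(by_vehicle$per_person),
      per_person_sd = stats::sd(by_vehicle$per_person))
  )
}
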