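# Canonical vocabularies: nutrients and their intake units, the five food
# vehicles, scenario names.  All tables are unit-checked against the
# registry at load time; fortificant levels are always mg per kg of vehicle
# and intakes are reported in the nutrient's registry unit.

VEHICLES <- c("wheat_flour", "maize_flour", "oil", "rice", "salt")

SCENARIOS <- c("no_fortification", "current", "improved_compliance",
               "aligned_standards", "aligned_improved",
               "aligned_improved_expanded")

PROGRAM_STATUS <- c("mandatory", "voluntary", "none")

#' Nutrient units registry
#'
#' The 13 modelled micronutrients and the unit in which daily intake of
#' each is expressed (micrograms for iodine, vitamin A, folate, vitamin
#' B12 and selenium; milligrams otherwise).  Fortification standard levels
#' are always mg of nutrient per kg of food vehicle regardless of the
#' intake unit; the conversion factor from mg to the registry unit is
#' carried in `to_unit`.
#'
#' @return A tibble with columns `nutrient`, `unit` (`"mg"` or `"ug"`) and
#'   `to_unit` (multiplier converting mg/day to unit/day).
#' @export
nutrient_units <- function() {
  ug <- c("vitamin_a", "folate", "vitamin_b12", "iodine", "selenium")
  nutrients <- c("calcium", "iron", "zinc", "vitamin_a", "folate",
                 "vitamin_b12", "thiamin", "riboflavin", "niacin",
                 "vitamin_b6", "vitamin_e", "iodine", "selenium")
  tibble::tibble(
    nutrient = nutrients,
    unit = ifelse(nutrients %in% ug, "ug", "mg"),
    to_unit = ifelse(nutrients %in% ug, 1000, 1)
  )
}

#' Canonical food vehicles
#' @return Character vector of the five vehicle labels.
#' @export
vehicle_names <- function() VEHICLES

#' Canonical scenario names
#' @return Character vector of the six scenario labels, ordered from no
#'   fortification to the most ambitious policy package.
#' @export
scenario_names <- function() SCENARIOS

check_scenario <- function(name) {
  bad <- setdiff(name, SCENARIOS)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown scenario name(s): ", paste(bad, collapse = ", ")))
  }
  invisible(name)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    rlang::abort(paste0(what, " table is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  invisible(df)
}
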