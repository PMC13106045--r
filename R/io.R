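# Reading and writing the pipeline's table dialects.  All tables are
# headered UTF-8 CSV; cost parameters are YAML.  `write_world()` /
# `read_world()` round-trip a full world directory, which is also the
# fixture format used by the test suite.

world_files <- c(
  intake = "intake_distributions.csv",
  programs = "fortification_programs.csv",
  standards = "current_standards.csv",
  guidelines = "guideline_standards.csv",
  requirements = "requirements.csv",
  uls = "upper_levels.csv",
  populations = "populations.csv",
  calorie_scaling = "calorie_scaling.csv",
  compounds = "compounds.csv",
  supply = "vehicle_supply.csv",
  facilities = "facilities.csv",
  regions = "regions.csv")

#' Read an intake-distribution table
#'
#' Accepts either dialect: family-native parameters (`family`, `param1`,
#' `param2`) or mean/CV (`family`, `mean`, `cv`); the dialect is detected
#' from the header.  Units are checked against the registry.
#'
#' @param path CSV path with columns `country`, `age_sex_group`,
#'   `nutrient` plus the distribution columns.
#' @param units Units registry (every nutrient must appear in it).
#' @return Tibble in mean/CV form.
#' @export
read_intake_table <- function(path, units = nutrient_units()) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("country", "age_sex_group", "nutrient", "family"),
                "intake")
  if (all(c("mean", "cv") %in% names(df))) {
    d <- dist_from_mean_cv(df$family, df$mean, df$cv)
  } else if (all(c("param1", "param2") %in% names(df))) {
    d <- dist_from_native(df$family, df$param1, df$param2)
  } else {
    rlang::abort("intake table needs either (mean, cv) or (param1, param2) columns")
  }
  unknown <- setdiff(unique(df$nutrient), units$nutrient)
  if (length(unknown) > 0) {
    rlang::abort(paste0("intake table has nutrient(s) outside the units registry: ",
                        paste(unknown, collapse = ", ")))
  }
  tibble::tibble(country = df$country, age_sex_group = df$age_sex_group,
                 nutrient = df$nutrient, family = d$family,
                 mean = d$mean, cv = d$cv)
}

#' Read cost parameters from YAML
#'
#' Missing fields take the documented defaults from
#' [default_cost_parameters()].
#'
#' @param path YAML file path.
#' @export
read_cost_parameters <- function(path) {
  merge_cost_parameters(yaml::read_yaml(path))
}

#' Write a world to a directory of CSV/YAML inputs
#'
#' Emits exactly the dialects the pipeline readers consume; used to write
#' canonical fixture worlds.
#'
#' @param world World list (see [generate_world()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(world_files)) {
    readr::write_csv(world[[nm]], file.path(dir, world_files[[nm]]), na = "")
  }
  yaml::write_yaml(world$cost_params, file.path(dir, "cost_parameters.yaml"))
  invisible(dir)
}

#' Read a world back from a directory
#'
#' @param dir Directory written by [write_world()] (or hand-prepared in
#'   the same dialects).
#' @return A world list.
#' @export
read_world <- function(dir) {
  world <- lapply(world_files, function(f) {
    readr::read_csv(file.path(dir, f), show_col_types = FALSE,
                    progress = FALSE)
  })
  world$intake <- read_intake_table(file.path(dir, world_files[["intake"]]))
  check_columns(world$programs,
                c("country", "vehicle", "status", "percap_intake",
                  "industrially_processed", "compliance"), "programme")
  check_columns(world$requirements,
                c("nutrient", "age_sex_group", "ar"), "requirements")
  if (!"req_cv" %in% names(world$requirements)) world$requirements$req_cv <- 0.1
  if (!"req_family" %in% names(world$requirements)) {
    world$requirements$req_family <- "normal"
  }
  world$requirements$req_cv[is.na(world$requirements$req_cv)] <- 0.1
  world$requirements$req_family[is.na(world$requirements$req_family)] <- "normal"
  check_columns(world$uls, c("nutrient", "age_sex_group", "ul"), "upper levels")
  bad_ul <- dplyr::inner_join(world$uls, world$requirements,
                              by = c("nutrient", "age_sex_group"))
  if (any(bad_ul$ul <= bad_ul$ar)) {
    rlang::abort("upper level must exceed the average requirement for the same stratum")
  }
  world$cost_params <- read_cost_parameters(file.path(dir, "cost_parameters.yaml"))
  world$config <- NULL
  world
}
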