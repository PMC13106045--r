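# Seeded generator of a miniature world with the statistical structure the
# analysis assumes: skewed usual-intake distributions centred loosely on
# requirements, GFDx-style programme indicators with realistic missingness,
# standards scattered above and below international guidelines, and
# mutually consistent population, scaling, supply and cost tables.  The
# generator matches structure, not geography.

# run code under a named seed without disturbing global RNG state
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

#' Default age-sex group labels
#'
#' 34 groups: 17 five-year age bands (0-4 through 80+) by sex.
#' @return Character vector of 34 labels like `"female_25-29"`.
#' @export
age_sex_groups <- function() {
  bands <- c(paste(seq(0, 75, 5), seq(4, 79, 5), sep = "-"), "80+")
  as.vector(outer(c("male", "female"), bands, paste, sep = "_"))
}

# female reproductive-age groups: skewed (lognormal) iron requirement
menstruating_groups <- function() {
  paste0("female_", c("15-19", "20-24", "25-29", "30-34", "35-39",
                      "40-44", "45-49"))
}

#' World-generation configuration
#'
#' Defaults give the miniature study world: 10 countries in 2 regions with
#' the full stratum structure (34 age-sex groups, 13 micronutrients, 5
#' vehicles).  Missingness rates for the industrially-processed and
#' compliance indicators echo the high-missingness pattern of real
#' programme registries (condiments worst); the generator always leaves at
#' least one observed value per vehicle so imputation is well-defined.
#'
#' @param n_countries Number of countries (>= 1).
#' @param n_regions Number of regions for the imputation hierarchy.
#' @param groups Age-sex group labels.
#' @param nutrients Nutrient labels (must be in the units registry).
#' @param seed Integer seed; same seed, same world.
#' @param ip_missingness,fc_missingness Named per-vehicle missingness
#'   probabilities in [0, 1).
#' @export
world_config <- function(n_countries = 10, n_regions = 2,
                         groups = age_sex_groups(),
                         nutrients = nutrient_units()$nutrient,
                         seed = 42,
                         ip_missingness = c(wheat_flour = 0.05,
                                            maize_flour = 0.3, oil = 0.7,
                                            rice = 0.25, salt = 0.8),
                         fc_missingness = c(wheat_flour = 0.25,
                                            maize_flour = 0.2, oil = 0.6,
                                            rice = 0.3, salt = 0.7)) {
  stopifnot(n_countries >= 1, n_regions >= 1,
            all(ip_missingness >= 0 & ip_missingness < 1),
            all(fc_missingness >= 0 & fc_missingness < 1))
  list(n_countries = n_countries, n_regions = n_regions, groups = groups,
       nutrients = nutrients, seed = seed,
       ip_missingness = ip_missingness, fc_missingness = fc_missingness)
}

# plausible adult average requirements (registry units/day) used as the
# anchor for both requirement and intake generation; synthetic values
base_requirements <- function() {
  tibble::tribble(
    ~nutrient,     ~ar,
    "calcium",     860,
    "iron",        8,
    "zinc",        10.2,
    "vitamin_a",   490,
    "folate",      250,
    "vitamin_b12", 2.0,
    "thiamin",     0.9,
    "riboflavin",  1.1,
    "niacin",      11,
    "vitamin_b6",  1.1,
    "vitamin_e",   10,
    "iodine",      107,
    "selenium",    45
  )
}

# harmonised ULs exist for seven nutrients only (synthetic values, adult)
base_uls <- function() {
  tibble::tribble(
    ~nutrient,   ~ul,
    "calcium",   2500,
    "iron",      45,
    "zinc",      40,
    "vitamin_a", 3000,
    "folate",    1000,
    "iodine",    600,
    "selenium",  400
  )
}

# age multiplier applied to both AR and UL (children need less)
age_factor <- function(group) {
  band <- sub("^(male|female)_", "", group)
  lo <- suppressWarnings(as.numeric(sub("-.*$|\\+$", "", band)))
  ifelse(lo < 5, 0.35, ifelse(lo < 10, 0.55, ifelse(lo < 15, 0.8, 1)))
}

#' Synthetic guideline fortification standards
#'
#' One international guideline level per vehicle x nutrient (mg of
#' nutrient per kg of vehicle) with the field's typical vehicle-nutrient
#' pairings; includes calcium in wheat flour, the costly seldom-practised
#' pairing probed by the calcium sensitivity analysis.
#' @export
guideline_standards <- function() {
  tibble::tribble(
    ~vehicle,      ~nutrient,     ~level_mg_per_kg,
    "wheat_flour", "iron",        30,
    "wheat_flour", "folate",      2.6,
    "wheat_flour", "zinc",        30,
    "wheat_flour", "vitamin_b12", 0.02,
    "wheat_flour", "thiamin",     2,
    "wheat_flour", "riboflavin",  3,
    "wheat_flour", "niacin",      20,
    "wheat_flour", "vitamin_b6",  3,
    "wheat_flour", "calcium",     1500,
    "maize_flour", "iron",        30,
    "maize_flour", "folate",      1.3,
    "maize_flour", "zinc",        30,
    "maize_flour", "vitamin_b12", 0.01,
    "maize_flour", "thiamin",     2,
    "maize_flour", "riboflavin",  2.5,
    "maize_flour", "niacin",      30,
    "oil",         "vitamin_a",   20,
    "oil",         "vitamin_e",   60,
    "rice",        "iron",        7,
    "rice",        "folate",      1.3,
    "rice",        "zinc",        6,
    "rice",        "vitamin_b12", 0.01,
    "rice",        "thiamin",     3.5,
    "rice",        "niacin",      35,
    "rice",        "vitamin_b6",  4,
    "salt",        "iodine",      40
  ) |>
    dplyr::left_join(default_compounds()[c("nutrient", "compound")],
                     by = "nutrient")
}

#' Synthetic compound specifications
#'
#' One fortificant compound per nutrient with a plausible elemental
#' activity (fraction of nutrient in the compound) and 2021 USD/kg price.
#' @export
default_compounds <- function() {
  tibble::tribble(
    ~compound,                      ~nutrient,     ~activity, ~price_usd_per_kg,
    "calcium_carbonate",            "calcium",     0.40,      1.5,
    "nafeedta",                     "iron",        0.13,      9,
    "zinc_oxide",                   "zinc",        0.80,      3.5,
    "retinyl_palmitate_250cws",     "vitamin_a",   0.075,     90,
    "folic_acid",                   "folate",      0.88,      55,
    "cyanocobalamin_premix",        "vitamin_b12", 0.001,     250,
    "thiamin_mononitrate",          "thiamin",     0.81,      30,
    "riboflavin_powder",            "riboflavin",  0.98,      55,
    "niacinamide",                  "niacin",      0.99,      12,
    "pyridoxine_hcl",               "vitamin_b6",  0.82,      30,
    "dl_alpha_tocopheryl_acetate",  "vitamin_e",   0.91,      25,
    "potassium_iodate",             "iodine",      0.59,      35,
    "sodium_selenite",              "selenium",    0.45,      40
  )
}

#' Generate a synthetic world
#'
#' Deterministic given the configured seed.  Intake means are drawn per
#' country x nutrient on a log scale around the stratum requirement so
#' baseline inadequacy spans (0, 1); CVs lie in [0.2, 0.8]; the family is
#' lognormal or gamma per nutrient.  Programme indicators are drawn in
#' observed-plausible ranges (FC in [0.1, 0.95], IP in [0.2, 1.0]) with
#' configured missingness; current standard levels scatter between 0.5x
#' and 1.5x the guideline so alignment has both binding and slack cases.
#' All tables are mutually consistent: every referenced stratum exists.
#'
#' @param config A [world_config()].
#' @return A named list of tibbles (`intake`, `programs`, `standards`,
#'   `guidelines`, `requirements`, `uls`, `populations`,
#'   `calorie_scaling`, `compounds`, `supply`, `facilities`, `regions`)
#'   plus `cost_params` (list) and the `config` itself.
#' @export
generate_world <- function(config = world_config()) {
  with_seed(config$seed, {
    countries <- sprintf("C%02d", seq_len(config$n_countries))
    regions <- tibble::tibble(
      country = countries,
      region = sprintf("R%d", (seq_along(countries) - 1) %% config$n_regions + 1))
    groups <- config$groups
    nutrients <- config$nutrients
    units <- nutrient_units()

    # requirements: adult anchor x age factor, slight sex difference;
    # skewed (lognormal, wider) iron requirement for menstruating women
    req <- tidyr::expand_grid(nutrient = nutrients, age_sex_group = groups) |>
      dplyr::left_join(base_requirements(), by = "nutrient") |>
      dplyr::mutate(
        ar = .data$ar * age_factor(.data$age_sex_group) *
          ifelse(startsWith(.data$age_sex_group, "male"), 1.05, 0.95),
        ar = ifelse(.data$nutrient == "iron" &
                      .data$age_sex_group %in% menstruating_groups(),
                    .data$ar * 1.6, .data$ar),
        req_cv = ifelse(.data$nutrient == "iron" &
                          .data$age_sex_group %in% menstruating_groups(),
                        0.25, 0.10),
        req_family = ifelse(.data$nutrient == "iron" &
                              .data$age_sex_group %in% menstruating_groups(),
                            "lognormal", "normal"))

    uls <- tidyr::expand_grid(nutrient = base_uls()$nutrient,
                              age_sex_group = groups) |>
      dplyr::left_join(base_uls(), by = "nutrient") |>
      dplyr::mutate(ul = .data$ul * age_factor(.data$age_sex_group))

    # populations: country sizes lognormal, group shares noisy-uniform
    pop <- tidyr::expand_grid(country = countries, age_sex_group = groups)
    country_size <- stats::setNames(stats::rlnorm(length(countries),
                                                  log(3e7), 0.8), countries)
    shares <- stats::runif(nrow(pop), 0.5, 1.5)
    pop$persons <- vapply(seq_len(nrow(pop)), function(i) {
      w <- shares[pop$country == pop$country[i]]
      country_size[[pop$country[i]]] * shares[i] / sum(w)
    }, numeric(1))

    # calorie ratios: adults eat more than children; normalised so the
    # population-weighted mean within each country is exactly 1
    scaling <- pop |>
      dplyr::mutate(raw = age_factor(.data$age_sex_group) *
                      ifelse(startsWith(.data$age_sex_group, "male"), 1.1, 0.9) *
                      stats::runif(dplyr::n(), 0.9, 1.1)) |>
      dplyr::group_by(.data$country) |>
      dplyr::mutate(calorie_ratio = .data$raw /
                      (sum(.data$raw * .data$persons) / sum(.data$persons))) |>
      dplyr::ungroup() |>
      dplyr::select("country", "age_sex_group", "calorie_ratio")

    # intake distributions: country x nutrient log-offset around the AR,
    # small extra stratum noise; family fixed per nutrient
    fam <- stats::setNames(
      rep(c("lognormal", "gamma"), length.out = length(nutrients)), nutrients)
    offset <- tidyr::expand_grid(country = countries, nutrient = nutrients) |>
      dplyr::mutate(log_offset = stats::rnorm(dplyr::n(), 0, 0.6))
    intake <- tidyr::expand_grid(country = countries,
                                 age_sex_group = groups,
                                 nutrient = nutrients) |>
      dplyr::left_join(offset, by = c("country", "nutrient")) |>
      dplyr::left_join(req[c("nutrient", "age_sex_group", "ar")],
                       by = c("nutrient", "age_sex_group")) |>
      dplyr::mutate(
        family = unname(fam[.data$nutrient]),
        mean = .data$ar * exp(.data$log_offset +
                                stats::rnorm(dplyr::n(), 0, 0.15)),
        cv = stats::runif(dplyr::n(), 0.2, 0.8)) |>
      dplyr::select("country", "age_sex_group", "nutrient", "family",
                    "mean", "cv")

    # programmes: status mix (salt iodisation is the most widespread),
    # vehicle-typical intake ranges, indicators with missingness but
    # always at least one observed value per vehicle
    progs <- tidyr::expand_grid(country = countries, vehicle = VEHICLES) |>
      dplyr::mutate(
        status = ifelse(.data$vehicle == "salt",
                        sample(PROGRAM_STATUS, dplyr::n(), TRUE,
                               prob = c(0.7, 0.1, 0.2)),
                        sample(PROGRAM_STATUS, dplyr::n(), TRUE,
                               prob = c(0.45, 0.2, 0.35))),
        percap_intake = dplyr::case_when(
          .data$vehicle == "wheat_flour" ~ stats::runif(dplyr::n(), 30, 350),
          .data$vehicle == "maize_flour" ~ stats::runif(dplyr::n(), 5, 250),
          .data$vehicle == "oil" ~ stats::runif(dplyr::n(), 5, 45),
          .data$vehicle == "rice" ~ stats::runif(dplyr::n(), 10, 350),
          .data$vehicle == "salt" ~ stats::runif(dplyr::n(), 4, 12)),
        industrially_processed = stats::runif(dplyr::n(), 0.2, 1.0),
        compliance = stats::runif(dplyr::n(), 0.1, 0.95))
    for (v in VEHICLES) {
      rows <- which(progs$vehicle == v)
      ip_miss <- stats::runif(length(rows)) < config$ip_missingness[[v]]
      fc_miss <- stats::runif(length(rows)) < config$fc_missingness[[v]]
      if (all(ip_miss)) ip_miss[1] <- FALSE
      if (all(fc_miss)) fc_miss[1] <- FALSE
      progs$industrially_processed[rows[ip_miss]] <- NA_real_
      progs$compliance[rows[fc_miss]] <- NA_real_
    }

    # current standards: active programmes fortify a subset of the
    # vehicle's guideline nutrients at 0.5-1.5x the guideline level;
    # calcium in wheat is seldom done
    gl <- guideline_standards()
    std <- progs |>
      dplyr::filter(.data$status != "none") |>
      dplyr::select("country", "vehicle") |>
      dplyr::inner_join(gl, by = "vehicle", relationship = "many-to-many") |>
      dplyr::mutate(keep = stats::runif(dplyr::n()) <
                      ifelse(.data$nutrient == "calcium", 0.15, 0.7),
                    level_mg_per_kg = .data$level_mg_per_kg *
                      stats::runif(dplyr::n(), 0.5, 1.5))
    # every active programme keeps at least one nutrient
    std <- std |>
      dplyr::group_by(.data$country, .data$vehicle) |>
      dplyr::mutate(keep = .data$keep | dplyr::row_number() == 1) |>
      dplyr::ungroup() |>
      dplyr::filter(.data$keep) |>
      dplyr::select("country", "vehicle", "nutrient", "level_mg_per_kg",
                    "compound")

    # supply consistent with per-capita intake and population; facilities
    # are input data drawn from a stated distribution
    country_pop <- stats::aggregate(persons ~ country, pop, sum)
    supply <- progs |>
      dplyr::left_join(country_pop, by = "country") |>
      dplyr::transmute(.data$country, .data$vehicle,
                       supply_tonnes = dplyr::coalesce(.data$percap_intake, 0) *
                         .data$persons * 365 / 1e6)
    facilities <- tidyr::expand_grid(country = countries, vehicle = VEHICLES) |>
      dplyr::mutate(facilities = 1 + stats::rpois(dplyr::n(), 5))

    list(intake = intake, programs = progs, standards = std,
         guidelines = gl, requirements = req, uls = uls,
         populations = tibble::as_tibble(pop),
         calorie_scaling = scaling, compounds = default_compounds(),
         supply = supply, facilities = facilities, regions = regions,
         cost_params = default_cost_parameters(), config = config)
  })
}

#' Generate a known-truth world with an analytic answer sheet
#'
#' Builds a deliberately degenerate miniature world whose adequacy and
#' contribution outputs have closed forms: point-mass intakes sitting at,
#' far below, and far above the requirement (prevalence 0.5, 1, 0); a
#' near-zero requirement CV stratum whose prevalence equals the intake CDF
#' at the AR (the cut-point limit); and a single-vehicle single-nutrient
#' programme whose intake contribution is the hand product
#' `F x IP x FC x D / 1000`.  The answer sheet carries the expected
#' values for comparison against a full pipeline run of the `current`
#' scenario.
#'
#' @return A list with `world` (same shape as [generate_world()]) and
#'   `answers` (tibble `scenario`, `country`, `age_sex_group`,
#'   `nutrient`, `quantity`, `expected`).
#' @export
generate_known_truth <- function() {
  countries <- c("kt_point_mid", "kt_point_low", "kt_point_high",
                 "kt_cutpoint", "kt_vehicle")
  groups <- c("male_25-29", "female_25-29")
  ar_iron <- 8; ar_zinc <- 10
  req <- tidyr::expand_grid(nutrient = c("iron", "zinc"),
                            age_sex_group = groups) |>
    dplyr::mutate(ar = ifelse(.data$nutrient == "iron", ar_iron, ar_zinc),
                  req_cv = ifelse(.data$nutrient == "iron", 0.10, 1e-9),
                  req_family = "normal")
  grid <- tidyr::expand_grid(country = countries, age_sex_group = groups,
                             nutrient = c("iron", "zinc"))
  intake <- grid |>
    dplyr::mutate(
      family = "lognormal",
      mean = dplyr::case_when(
        .data$country == "kt_point_mid" & .data$nutrient == "iron" ~ ar_iron,
        .data$country == "kt_point_low" & .data$nutrient == "iron" ~ 0.2 * ar_iron,
        .data$country == "kt_point_high" & .data$nutrient == "iron" ~ 2 * ar_iron,
        .data$nutrient == "iron" ~ 1.1 * ar_iron,
        .data$country == "kt_cutpoint" ~ 1.2 * ar_zinc,
        TRUE ~ 1.3 * ar_zinc),
      cv = dplyr::case_when(
        startsWith(.data$country, "kt_point") & .data$nutrient == "iron" ~ 1e-9,
        .data$country == "kt_cutpoint" & .data$nutrient == "zinc" ~ 0.5,
        TRUE ~ 0.4))
  progs <- tidyr::expand_grid(country = countries, vehicle = VEHICLES) |>
    dplyr::mutate(
      status = ifelse(.data$country == "kt_vehicle" &
                        .data$vehicle == "wheat_flour", "mandatory", "none"),
      percap_intake = ifelse(.data$vehicle == "wheat_flour", 100, 10),
      industrially_processed = 0.8, compliance = 0.5)
  std <- tibble::tibble(country = "kt_vehicle", vehicle = "wheat_flour",
                        nutrient = "iron", level_mg_per_kg = 30,
                        compound = "nafeedta")
  pop <- tidyr::expand_grid(country = countries, age_sex_group = groups) |>
    dplyr::mutate(persons = 1000)
  scaling <- tidyr::expand_grid(country = countries, age_sex_group = groups) |>
    dplyr::mutate(calorie_ratio = 1)
  cut_pars <- dist_native_params("lognormal", 1.2 * ar_zinc, 0.5)
  answers <- dplyr::bind_rows(
    tibble::tibble(country = c("kt_point_mid", "kt_point_low", "kt_point_high"),
                   nutrient = "iron", quantity = "prev_inadequate",
                   expected = c(0.5, 1, 0)),
    tibble::tibble(country = "kt_cutpoint", nutrient = "zinc",
                   quantity = "prev_inadequate",
                   expected = stats::plnorm(ar_zinc, cut_pars$param1,
                                            cut_pars$param2)),
    tibble::tibble(country = "kt_vehicle", nutrient = "iron",
                   quantity = "contribution",
                   expected = 100 * 0.8 * 0.5 * 30 / 1000)) |>
    tidyr::expand_grid(age_sex_group = groups) |>
    dplyr::mutate(scenario = "current") |>
    dplyr::select("scenario", "country", "age_sex_group", "nutrient",
                  "quantity", "expected")
  world <- list(
    intake = intake, programs = progs, standards = std,
    guidelines = guideline_standards(),
    requirements = req,
    uls = tibble::tibble(nutrient = character(), age_sex_group = character(),
                         ul = numeric()),
    populations = pop, calorie_scaling = scaling,
    compounds = default_compounds(),
    supply = tidyr::expand_grid(country = countries, vehicle = VEHICLES) |>
      dplyr::mutate(supply_tonnes = 1000),
    facilities = tidyr::expand_grid(country = countries, vehicle = VEHICLES) |>
      dplyr::mutate(facilities = 3),
    regions = tibble::tibble(country = countries, region = "R1"),
    cost_params = default_cost_parameters(),
    config = NULL)
  list(world = world, answers = answers)
}
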