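make_programs <- function(...) {
  tibble::tibble(...)
}

test_that("imputation follows the region-then-global median hierarchy", {
  progs <- make_programs(
    country = c("A", "B", "C", "D"),
    vehicle = "wheat_flour", status = "mandatory",
    percap_intake = 100,
    industrially_processed = c(0.6, 0.8, NA, 0.7),
    compliance = c(NA, NA, NA, 0.5))
  regions <- tibble::tibble(country = c("A", "B", "C", "D"),
                            region = c("R1", "R1", "R1", "R2"))
  out <- impute_missing(progs, regions)
  # C's region peers have IP {0.6, 0.8}
  expect_equal(out$industrially_processed[out$country == "C"], 0.7)
  expect_true(out$ip_imputed[out$country == "C"])
  # no observed FC in R1: global median fallback (only 0.5 observed)
  expect_equal(out$compliance[out$country == "A"], 0.5)
  expect_false(out$fc_imputed[out$country == "D"])
  # idempotent, and identity when nothing is missing
  expect_identical(impute_missing(out, regions), out)
  none_missing <- make_programs(
    country = "A", vehicle = "oil", status = "voluntary",
    percap_intake = 20, industrially_processed = 0.9, compliance = 0.4)
  out2 <- impute_missing(none_missing, regions)
  expect_identical(out2$industrially_processed, 0.9)
  expect_false(out2$ip_imputed)
  # a vehicle with no observed value anywhere is a configuration error
  all_na <- make_programs(
    country = c("A", "B"), vehicle = "rice", status = "mandatory",
    percap_intake = 50, industrially_processed = NA_real_,
    compliance = 0.5)
  expect_error(impute_missing(all_na, regions), "rice")
})

test_that("vehicle intake scales by calorie ratios and averages back", {
  w <- tiny_world()
  progs <- impute_missing(w$programs, w$regions)
  f <- scale_vehicle_intake(progs, w$calorie_scaling)
  joined <- dplyr::inner_join(f, w$populations,
                              by = c("country", "age_sex_group")) |>
    dplyr::inner_join(progs[c("country", "vehicle", "percap_intake")],
                      by = c("country", "vehicle")) |>
    dplyr::group_by(country, vehicle) |>
    dplyr::summarise(
      wmean = sum(intake_g_day * persons) / sum(persons),
      percap = percap_intake[1], .groups = "drop")
  expect_equal(joined$wmean, joined$percap, tolerance = 1e-6)
  # missing country falls back to ratio 1 with a warning
  lone <- make_programs(country = "ZZ", vehicle = "oil", status = "mandatory",
                        percap_intake = 30, industrially_processed = 1,
                        compliance = 1)
  expect_warning(f2 <- scale_vehicle_intake(lone, w$calorie_scaling), "ZZ")
  expect_true(all(f2$intake_g_day == 30))
})

test_that("the contribution equation multiplies and converts units", {
  scaling <- tibble::tibble(age_sex_group = "adult", calorie_ratio = 1)
  progs <- make_programs(
    country = "A", vehicle = c("wheat_flour", "salt"),
    status = "mandatory", percap_intake = c(100, 10),
    industrially_processed = 1, compliance = 1)
  std <- tibble::tibble(
    country = "A", vehicle = c("wheat_flour", "salt"),
    nutrient = c("iron", "iodine"), level_mg_per_kg = c(30, 40),
    compound = c("nafeedta", "potassium_iodate"))
  out <- fortificant_contribution(progs, std, scaling)
  # 100 g/day x 30 mg/kg / 1000 = 3 mg/day of iron
  expect_equal(out$contribution[out$nutrient == "iron"], 3)
  # iodine is registered in micrograms: 10 x 40 / 1000 mg -> 400 ug
  expect_equal(out$contribution[out$nutrient == "iodine"], 400)
  # zero compliance kills the contribution
  progs0 <- dplyr::mutate(progs, compliance = 0)
  out0 <- fortificant_contribution(progs0, std, scaling)
  expect_true(all(out0$contribution == 0))
  # unknown nutrient is a configuration error
  bad <- dplyr::mutate(std, nutrient = c("iron", "unobtainium"))
  expect_error(fortificant_contribution(progs, bad, scaling), "unobtainium")
})

test_that("contribution is linear per vehicle and sums across vehicles", {
  withr::with_seed(61, {
    scaling <- tibble::tibble(age_sex_group = "adult", calorie_ratio = 1)
    progs <- make_programs(
      country = "A", vehicle = c("wheat_flour", "rice", "maize_flour"),
      status = c("mandatory", "voluntary", "mandatory"),
      percap_intake = runif(3, 20, 200),
      industrially_processed = runif(3, 0.3, 1),
      compliance = runif(3, 0.2, 0.9))
    std <- tibble::tibble(
      country = "A", vehicle = c("wheat_flour", "rice", "maize_flour"),
      nutrient = "iron", level_mg_per_kg = runif(3, 10, 60),
      compound = "nafeedta")
    out <- fortificant_contribution(progs, std, scaling)
    hand <- sum(progs$percap_intake * progs$industrially_processed *
                  progs$compliance * std$level_mg_per_kg / 1000)
    expect_equal(out$contribution, hand, tolerance = 1e-14)
    # doubling one vehicle's compliance doubles exactly that term
    progs2 <- progs
    progs2$compliance[2] <- 2 * progs2$compliance[2]
    out2 <- fortificant_contribution(progs2, std, scaling)
    term2 <- progs$percap_intake[2] * progs$industrially_processed[2] *
      progs$compliance[2] * std$level_mg_per_kg[2] / 1000
    expect_equal(out2$contribution - out$contribution, term2,
                 tolerance = 1e-14)
  })
})

test_that("scenario rules rewrite compliance and standards as declared", {
  w <- tiny_world()
  progs <- impute_missing(w$programs, w$regions)
  # current: identity
  cur <- apply_scenario(progs, w$standards, w$guidelines,
                        scenario_spec("current"))
  expect_equal(cur$programs$compliance, progs$compliance)
  expect_identical(cur$standards, w$standards)
  # no fortification: compliance zeroed everywhere
  none <- apply_scenario(progs, w$standards, w$guidelines,
                         scenario_spec("no_fortification"))
  expect_true(all(none$programs$compliance == 0))
  # improved compliance: floor at 0.9, never degrade above it
  p <- progs
  p$compliance[1] <- 0.75; p$compliance[2] <- 0.95
  imp <- apply_scenario(p, w$standards, w$guidelines,
                        scenario_spec("improved_compliance"))
  live <- imp$programs$status != "none"
  expect_true(all(imp$programs$compliance[live] >= 0.9))
  expect_equal(imp$programs$compliance[2], max(0.95, 0.9))
  # alignment under the max rule never lowers a level and adds
  # guideline nutrients missing from the current standard
  ali <- apply_scenario(progs, w$standards, w$guidelines,
                        scenario_spec("aligned_standards"))
  merged <- dplyr::inner_join(ali$standards, w$standards,
                              by = c("country", "vehicle", "nutrient"),
                              suffix = c("_new", "_old"))
  expect_true(all(merged$level_mg_per_kg_new >= merged$level_mg_per_kg_old))
  merged_gl <- dplyr::inner_join(ali$standards, w$guidelines,
                                 by = c("vehicle", "nutrient"),
                                 suffix = c("_new", "_gl"))
  expect_true(all(merged_gl$level_mg_per_kg_new >=
                    merged_gl$level_mg_per_kg_gl))
  # replace rule: standards become exactly the guideline levels
  rep <- apply_scenario(progs, w$standards, w$guidelines,
                        scenario_spec("aligned_standards",
                                      align_rule = "replace_with_guideline"))
  merged_rep <- dplyr::inner_join(rep$standards, w$guidelines,
                                  by = c("vehicle", "nutrient"),
                                  suffix = c("_new", "_gl"))
  expect_equal(merged_rep$level_mg_per_kg_new, merged_rep$level_mg_per_kg_gl)
  # alignment without guidelines is a configuration error
  expect_error(apply_scenario(progs, w$standards, NULL,
                              scenario_spec("aligned_standards")),
               "guideline")
})

test_that("expansion adds mandatory programmes only where eligible", {
  params <- expansion_params()
  expect_true(expansion_eligible(0.5, 200, 0.8, "wheat_flour", params))
  expect_false(expansion_eligible(0, 200, 0.8, "wheat_flour", params))
  expect_false(expansion_eligible(0.5, 20, 0.8, "wheat_flour", params))
  expect_false(expansion_eligible(0.5, 200, 0.3, "wheat_flour", params))
  # condiment thresholds are vehicle-specific
  expect_true(expansion_eligible(0.5, 6, 0.8, "salt", params))

  w <- tiny_world()
  progs <- impute_missing(w$programs, w$regions)
  run <- tiny_run()
  exp_sc <- apply_scenario(progs, w$standards, w$guidelines,
                           scenario_spec("aligned_improved_expanded"),
                           baseline_prev = run$country_prevalence)
  added <- dplyr::filter(exp_sc$programs, added)
  untouched <- dplyr::filter(exp_sc$programs, !added)
  expect_true(all(added$status == "mandatory"))
  expect_true(all(added$compliance == 0.9))
  # every added programme carries the full guideline standard
  for (i in seq_len(nrow(added))) {
    got <- dplyr::filter(exp_sc$standards, country == added$country[i],
                         vehicle == added$vehicle[i])
    want <- dplyr::filter(w$guidelines, vehicle == added$vehicle[i])
    expect_setequal(got$nutrient, want$nutrient)
  }
  # non-added rows keep their original status
  orig <- progs[order(progs$country, progs$vehicle), ]
  kept <- untouched[order(untouched$country, untouched$vehicle), ]
  expect_equal(kept$status,
               orig$status[paste(orig$country, orig$vehicle) %in%
                             paste(kept$country, kept$vehicle)])
  expect_error(apply_scenario(progs, w$standards, w$guidelines,
                              scenario_spec("aligned_improved_expanded")),
               "baseline")
})
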