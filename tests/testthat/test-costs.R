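zero_markups <- list(shipping = 0, taxes_duties = 0, domestic_logistics = 0)

test_that("premix cost per tonne prices compound mass through markups", {
  compounds <- tibble::tibble(
    compound = c("c1", "c2", "c3"), nutrient = c("iron", "zinc", "folate"),
    activity = c(0.5, 0.8, 0.9), price_usd_per_kg = c(10, 4, 50))
  std1 <- tibble::tibble(nutrient = "iron", level_mg_per_kg = 30,
                         compound = "c1")
  expect_equal(premix_cost_per_tonne(std1, compounds, zero_markups), 0.60)
  expect_equal(premix_cost_per_tonne(std1[0, ], compounds), 0)
  std3 <- tibble::tibble(nutrient = c("iron", "zinc", "folate"),
                         level_mg_per_kg = c(30, 50, 2.6),
                         compound = c("c1", "c2", "c3"))
  base <- 30 / 0.5 / 1000 * 10 + 50 / 0.8 / 1000 * 4 + 2.6 / 0.9 / 1000 * 50
  got <- premix_cost_per_tonne(std3, compounds,
                               list(shipping = 0.1, taxes_duties = 0.05,
                                    domestic_logistics = 0.08))
  expect_equal(got, base * 1.1 * 1.05 * 1.08)
  # missing compound spec names the nutrient
  std_bad <- tibble::tibble(nutrient = "iodine", level_mg_per_kg = 40,
                            compound = "kio3")
  expect_error(premix_cost_per_tonne(std_bad, compounds), "iodine")
})

test_that("fortified tonnage is supply x IP x FC", {
  expect_equal(fortified_tonnage(1000, 0.8, 0.5), 400)
  expect_equal(fortified_tonnage(1000, 0.8, 0), 0)
  expect_equal(fortified_tonnage(1000, 0.8, 0.9) /
                 fortified_tonnage(1000, 0.8, 0.5), 1.8)
  expect_error(fortified_tonnage(1000, 1.2, 0.5), "IP and FC")
})

test_that("annualisation is the annuity equivalent of the capital cost", {
  expect_equal(annualise(1000, 10, 0), 100)       # straight line
  expect_equal(annualise(1000, 1, 0.03), 1030)    # single period
  # the annual payment whose present value matches the capital
  a <- annualise(1000, 10, 0.03)
  pv <- function(pay) sum(pay / (1.03)^(1:10)) - 1000
  root <- stats::uniroot(pv, c(1, 1000), tol = 1e-10)$root
  expect_equal(a, root, tolerance = 1e-8)
  expect_error(annualise(1000, 0, 0.03), "life")
})

test_that("industry and government costs assemble their line items", {
  params <- default_cost_parameters()
  expect_equal(industry_cost(0, params), 0)
  only_labour <- utils::modifyList(params, list(industry_unit_costs = list(
    fortification_equipment = 0, qaqc_equipment = 0, qaqc_supplies = 0,
    labour = 500, training = 0, management_overhead = 0)))
  expect_equal(industry_cost(1, only_labour), 500)
  expect_equal(industry_cost(7, params), 7 * industry_cost(1, params))
  only_sm <- utils::modifyList(params, list(government_unit_costs = list(
    monitoring_equipment = 0, monitoring_supplies = 0, monitoring_labour = 0,
    social_marketing = 200, training = 0, management_overhead = 0,
    planning_launch = 0)))
  expect_equal(government_cost(FALSE, only_sm), 200)
  # new programmes add exactly the annualised planning/launch cost
  expect_equal(government_cost(TRUE, params) - government_cost(FALSE, params),
               annualise(params$government_unit_costs$planning_launch,
                         params$planning_life_yr, params$discount_rate))
  expect_equal(government_cost(TRUE, only_sm), government_cost(FALSE, only_sm))
})

test_that("scenario costs satisfy the additivity and share identities", {
  w <- tiny_world()
  run <- tiny_run()
  bd <- run$cost_breakdown
  expect_equal(bd$premix + bd$industry + bd$government, bd$total)
  for (sc in scenario_names()) {
    cs <- dplyr::filter(run$cost_summary, scenario == sc)
    tot <- sum(cs$total)
    if (tot > 0) expect_equal(sum(cs$share_pct), 100, tolerance = 1e-9)
    g <- dplyr::filter(run$global_summary, scenario == sc)
    expect_equal(g$cost_total, tot, tolerance = 1e-9)
    expect_equal(g$cost_total, g$cost_premix + g$cost_industry +
                   g$cost_government)
  }
  # no fortification costs nothing
  expect_equal(run$global_summary$cost_total[
    run$global_summary$scenario == "no_fortification"], 0)
  # a single active programme carries a 100% vehicle share
  kt <- generate_known_truth()$world
  progs <- impute_missing(kt$programs, kt$regions)
  cs <- scenario_costs(progs, kt$standards, kt$compounds, kt$supply,
                       kt$facilities, kt$populations, kt$cost_params)
  expect_equal(cs$summary$by_vehicle$share_pct[
    cs$summary$by_vehicle$vehicle == "wheat_flour"], 100)
  # doubling compound prices doubles premix cost exactly
  comp2 <- dplyr::mutate(kt$compounds, price_usd_per_kg = 2 * price_usd_per_kg)
  cs2 <- scenario_costs(progs, kt$standards, comp2, kt$supply,
                        kt$facilities, kt$populations, kt$cost_params)
  expect_equal(cs2$summary$premix, 2 * cs$summary$premix)
  expect_equal(cs2$summary$industry, cs$summary$industry)
})

test_that("cost monotonicity follows programme intensity", {
  g <- tiny_run()$global_summary
  cost <- function(sc) g$cost_total[g$scenario == sc]
  expect_lte(cost("current"), cost("improved_compliance"))
  expect_lte(cost("aligned_improved"), cost("aligned_improved_expanded"))
})
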