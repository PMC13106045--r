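# Shared fixtures: a reduced synthetic world (4 countries, 6 age-sex
# groups, 6 nutrients) keeps pipeline-level tests fast while exercising
# both distribution families, both sexes, children and adults, and
# nutrients with and without a harmonised UL.

tiny_groups <- function() {
  c("male_25-29", "female_25-29", "male_5-9",
    "female_30-34", "male_60-64", "female_0-4")
}

tiny_nutrients <- function() {
  c("iron", "zinc", "folate", "calcium", "iodine", "vitamin_a")
}

tiny_config <- function(seed = 7, ...) {
  world_config(n_countries = 4, n_regions = 2, groups = tiny_groups(),
               nutrients = tiny_nutrients(), seed = seed, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

tiny_world <- function() {
  if (is.null(.fixture_cache$tiny)) {
    .fixture_cache$tiny <- generate_world(tiny_config())
  }
  .fixture_cache$tiny
}

tiny_run <- function() {
  if (is.null(.fixture_cache$tiny_run)) {
    .fixture_cache$tiny_run <- run_scenarios(tiny_world())
  }
  .fixture_cache$tiny_run
}

# quadrature moments straight from the density, independent of the
# closed-form parameter maps
quadrature_moments <- function(family, mean, cv) {
  upper <- qintake(1 - 1e-12, family, mean, cv)
  m <- stats::integrate(function(x) x * dintake(x, family, mean, cv),
                        0, upper, rel.tol = 1e-10)$value
  v <- stats::integrate(function(x) (x - m)^2 * dintake(x, family, mean, cv),
                        0, upper, rel.tol = 1e-10)$value
  c(mean = m, sd = sqrt(v))
}
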