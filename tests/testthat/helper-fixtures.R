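# Shared fixtures: a small hand-built food universe, matching purchases and
# strata, a scaled-down simulation configuration, and a direct stratum-summary
# generator for testing the statistical layer in isolation.

test_items <- function() {
  tibble::tribble(
    ~item_code, ~name, ~nova_group, ~subgroup, ~is_beef,
    ~energy_density, ~edible_fraction, ~carbon_intensity, ~water_intensity,
    "A1", "fresh beef cut", 1L, "beef", TRUE, 200, 0.8, 26000, 15000,
    "A2", "rice", 1L, "cereals", FALSE, 360, 1.0, 2000, 2500,
    "A3", "soy oil", 2L, "oils and fats", FALSE, 900, 1.0, 100, 100,
    "A4", "bread", 3L, "breads", FALSE, 300, 1.0, 1000, 800,
    "A5", "soft drink", 4L, "soft drinks", FALSE, 40, 1.0, 400, 500,
    "A6", "filled cookie", 4L, "cookies and cakes", FALSE, 480, 1.0, 1500, 1200
  )
}

test_strata <- function(n = 2) {
  tibble::tibble(
    stratum_id = sprintf("S%02d", seq_len(n)),
    n_households = rep(2L, n),
    n_residents = rep(5L, n),
    expansion_weight = rep(100, n),
    income = rep(2000, n),
    area = rep("urban", n),
    region = rep("Southeast", n),
    out_of_home_share = rep(10, n)
  )
}

test_purchases <- function() {
  tibble::tibble(
    household_id = c("H1", "H1", "H2", "H2", "H2"),
    stratum_id = c("S01", "S01", "S02", "S02", "S02"),
    item_code = c("A1", "A2", "A2", "A5", "A6"),
    quantity = c(0.5, 2, 3, 4, 1)
  )
}

# Simulation configuration scaled down for fast repeated runs; stratum-level
# statistics are unaffected by the household count.
small_sim_config <- function(seed, ...) {
  args <- list(...)
  defaults <- list(
    seed = seed, n_strata = 100L, households_range = c(2L, 5L), n_items = 20L
  )
  do.call(simulation_config, utils::modifyList(defaults, args))
}

# Stratum summaries generated directly in outcome space, bypassing the
# purchase-level machinery: outcome = intercept + linear exposure effects
# (+ optional product term) + Gaussian noise. Used to test the regression,
# trend, interaction and scenario layers against known coefficients.
direct_data <- function(n = 120, seed = 1, effect_beef = 0, effect_upf = 0,
                        effect_interaction = 0, noise = 30) {
  withr::with_seed(seed, {
    regions <- c("Southeast", "North", "Northeast", "South", "Midwest")
    profiles <- tibble::tibble(
      stratum_id = sprintf("T%04d", seq_len(n)),
      n_households = 2L,
      n_residents = 5L,
      expansion_weight = stats::rlnorm(n, log(1000), 0.5),
      income = stats::rlnorm(n, log(2000), 0.5),
      area = sample(c("urban", "rural"), n, replace = TRUE, prob = c(0.8, 0.2)),
      region = sample(regions, n, replace = TRUE),
      out_of_home_share = stats::runif(n, 0, 40)
    )
    beef <- stats::runif(n, 3, 8.2)
    upf <- stats::runif(n, 10.1, 28.1)
    y <- 800 + effect_beef * beef + effect_upf * upf +
      effect_interaction * (beef - mean(beef)) * (upf - mean(upf)) +
      stats::rnorm(n, 0, noise)
    summaries <- tibble::tibble(
      stratum_id = profiles$stratum_id,
      energy = 1200,
      carbon = y * 1.2,
      water = y,
      pct_energy_upf = upf,
      pct_energy_beef = beef,
      carbon_per_1000kcal = y,
      water_per_1000kcal = 0.9 * y + stats::rnorm(n, 0, noise / 3)
    )
    list(summaries = summaries, profiles = profiles)
  })
}

both_assignments <- function(summaries, profiles, weighted = TRUE) {
  list(
    beef = assign_exposure_quintiles(summaries, profiles, "beef", weighted = weighted),
    upf = assign_exposure_quintiles(summaries, profiles, "upf", weighted = weighted)
  )
}

write_tables_tmp <- function(items, purchases, strata, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  paths <- list(
    reference = file.path(dir, "food_reference.csv"),
    purchases = file.path(dir, "purchases.csv"),
    strata = file.path(dir, "strata.csv"),
    outdir = file.path(dir, "out")
  )
  write_food_reference(items, paths$reference)
  write_purchases(purchases, paths$purchases)
  write_strata(strata, paths$strata)
  paths
}
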