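# Footprint accounting: energy on the edible portion, footprints on the full
# as-purchased mass, per-capita daily conversion, stratum summaries and the
# Nova contribution table.

test_that("item_energy applies the edible fraction and kcal conversion", {
  item <- tibble::tibble(edible_fraction = 1, energy_density = 100)
  expect_equal(item_energy(1, item), 1000)
  expect_equal(item_energy(0, item), 0)
  item2 <- tibble::tibble(edible_fraction = 0.5, energy_density = 250)
  expect_equal(item_energy(2, item2), 2500) # 2 * 0.5 * 10 * 250
  expect_error(item_energy(-1, item), ">= 0")
})

test_that("item_footprints use the full purchased mass, not the edible portion", {
  item <- tibble::tibble(
    edible_fraction = 1, carbon_intensity = 2000, water_intensity = 500
  )
  fp <- item_footprints(1, item)
  expect_equal(fp$carbon_g, 2000)
  expect_equal(fp$water_l, 500)

  # halving the edible fraction leaves the footprint unchanged
  item$edible_fraction <- 0.5
  expect_equal(item_footprints(1, item)$carbon_g, 2000)

  item3 <- tibble::tibble(
    edible_fraction = 0.8, carbon_intensity = 26000, water_intensity = 0
  )
  expect_equal(item_footprints(0.25, item3)$carbon_g, 6500)
})

test_that("per_capita_daily divides by 7 days then by residents", {
  expect_equal(per_capita_daily(7000, 1), 1000)
  expect_equal(per_capita_daily(0, 3), 0)
  expect_equal(per_capita_daily(4900, 7), 100)
  expect_error(per_capita_daily(10, 0), ">= 1")
})

test_that("summarise_stratum composes energy, footprints and exposure shares", {
  items <- tibble::tibble(
    item_code = "B1", name = "x", nova_group = 1L, subgroup = "cereals",
    is_beef = FALSE, energy_density = 100, edible_fraction = 1,
    carbon_intensity = 1000, water_intensity = 200
  )
  purchases <- tibble::tibble(
    household_id = "H1", stratum_id = "S01", item_code = "B1", quantity = 7
  )
  profile <- test_strata(1)
  profile$n_residents <- 1L
  profile$n_households <- 1L
  s <- summarise_stratum(purchases, items, profile)
  expect_equal(s$energy, 1000)
  expect_equal(s$carbon, 1000)
  expect_equal(s$water, 200)
  expect_equal(s$carbon_per_1000kcal, 1000)
  expect_equal(s$water_per_1000kcal, 200)
  expect_equal(s$pct_energy_upf, 0)
  expect_equal(s$pct_energy_beef, 0)
})

test_that("exposure shares are percentages of total energy", {
  # beef item supplying 52 of 1000 kcal -> 5.2 % beef energy share
  items <- tibble::tibble(
    item_code = c("B1", "B2"),
    name = c("beef", "rice"),
    nova_group = c(1L, 1L),
    subgroup = c("beef", "cereals"),
    is_beef = c(TRUE, FALSE),
    energy_density = c(200, 360),
    edible_fraction = c(1, 1),
    carbon_intensity = c(26000, 2000),
    water_intensity = c(15000, 2500)
  )
  purchases <- tibble::tibble(
    household_id = "H1", stratum_id = "S01",
    item_code = c("B1", "B2"),
    quantity = c(52 / 2000, 948 / 3600) # 52 kcal and 948 kcal
  )
  profile <- test_strata(1)
  s <- summarise_stratum(purchases, items, profile)
  expect_equal(s$pct_energy_beef, 5.2)
  expect_equal(s$pct_energy_upf, 0)
})

test_that("zero-energy strata get NA intensities with a warning and strata with no purchases get zero totals", {
  items <- test_items()
  purchases <- tibble::tibble(
    household_id = "H1", stratum_id = "S01", item_code = "A2", quantity = 0
  )
  strata <- test_strata(2)
  expect_warning(s <- summarise_strata(purchases, items, strata), "zero total energy")
  expect_equal(s$energy, c(0, 0))
  expect_true(all(is.na(s$carbon_per_1000kcal)))
  expect_true(all(is.na(s$pct_energy_beef)))
})

test_that("stratum summaries equal a brute-force per-record oracle", {
  # randomized small inputs; the oracle loops over records with the unit
  # operations and aggregates by hand
  for (seed in 1:20) {
    withr::with_seed(seed, {
      items <- test_items()
      n_rec <- sample(5:25, 1)
      strata <- test_strata(sample(2:3, 1))
      purchases <- tibble::tibble(
        household_id = sprintf("H%d", sample(1:4, n_rec, replace = TRUE)),
        stratum_id = sample(strata$stratum_id, n_rec, replace = TRUE),
        item_code = sample(items$item_code, n_rec, replace = TRUE),
        quantity = stats::runif(n_rec, 0, 5)
      )
    })
    got <- suppressWarnings(summarise_strata(purchases, items, strata))
    for (sid in strata$stratum_id) {
      energy <- carbon <- water <- beef_e <- upf_e <- 0
      for (i in seq_len(nrow(purchases))) {
        if (purchases$stratum_id[i] != sid) next
        it <- items[items$item_code == purchases$item_code[i], ]
        e <- item_energy(purchases$quantity[i], it)
        fp <- item_footprints(purchases$quantity[i], it)
        energy <- energy + e
        carbon <- carbon + fp$carbon_g
        water <- water + fp$water_l
        if (it$is_beef) beef_e <- beef_e + e
        if (it$nova_group == 4L) upf_e <- upf_e + e
      }
      n_res <- strata$n_residents[strata$stratum_id == sid]
      row <- got[got$stratum_id == sid, ]
      expect_equal(row$energy, per_capita_daily(energy, n_res))
      expect_equal(row$carbon, per_capita_daily(carbon, n_res))
      expect_equal(row$water, per_capita_daily(water, n_res))
      if (energy > 0) {
        expect_equal(row$pct_energy_beef, beef_e / energy * 100)
        expect_equal(row$pct_energy_upf, upf_e / energy * 100)
        expect_equal(row$carbon_per_1000kcal, carbon / energy * 1000)
      }
    }
  }
})

test_that("increasing any quantity never decreases a footprint and scaling edible fraction only scales energy", {
  items <- test_items()
  strata <- test_strata(1)
  withr::with_seed(5, {
    purchases <- tibble::tibble(
      household_id = "H1", stratum_id = "S01",
      item_code = items$item_code, quantity = stats::runif(6, 0.1, 3)
    )
  })
  base <- summarise_strata(purchases, items, strata)
  for (i in seq_len(nrow(purchases))) {
    bumped <- purchases
    bumped$quantity[i] <- bumped$quantity[i] + 1
    s <- summarise_strata(bumped, items, strata)
    expect_gte(s$carbon, base$carbon)
    expect_gte(s$water, base$water)
  }
  # edible-fraction asymmetry
  alpha <- 0.5
  scaled_items <- items
  scaled_items$edible_fraction <- items$edible_fraction * alpha
  s <- summarise_strata(purchases, scaled_items, strata)
  expect_equal(s$energy, base$energy * alpha)
  expect_equal(s$carbon, base$carbon)
  expect_equal(s$water, base$water)
})

test_that("footprint_energy_ratio is share over share, undefined at zero energy", {
  for (x in c(0.3, 5.2, 48.7, 100)) {
    expect_equal(footprint_energy_ratio(x, x), 1)
  }
  expect_true(is.na(footprint_energy_ratio(10, 0)))
  expect_error(footprint_energy_ratio(-1, 5), ">= 0")
  # coherence: ratio > 1 iff footprint share exceeds energy share
  withr::with_seed(9, {
    pf <- stats::runif(50, 0, 100)
    pe <- stats::runif(50, 0.1, 100)
  })
  r <- footprint_energy_ratio(pf, pe)
  expect_equal(r > 1, pf > pe)
})

test_that("contribution table conserves percentages and pools by expansion weight", {
  items <- test_items()
  strata <- test_strata(2)

  # one-group universe: that group takes 100 % of everything
  one <- tibble::tibble(
    household_id = "H1", stratum_id = "S01", item_code = "A2", quantity = 2
  )
  tab <- contribution_table(one, items, strata[1, ])
  g1 <- tab[tab$level == "group" & tab$nova_group == 1L, ]
  expect_equal(g1$pct_energy, 100)
  expect_equal(g1$pct_carbon, 100)
  expect_equal(g1$pct_water, 100)

  # generic universe: group percentages each sum to 100
  withr::with_seed(3, {
    purchases <- tibble::tibble(
      household_id = "H1",
      stratum_id = sample(strata$stratum_id, 12, replace = TRUE),
      item_code = sample(items$item_code, 12, replace = TRUE),
      quantity = stats::runif(12, 0.2, 4)
    )
  })
  tab <- contribution_table(purchases, items, strata)
  grp <- tab[tab$level == "group", ]
  expect_equal(sum(grp$pct_energy), 100, tolerance = 1e-10)
  expect_equal(sum(grp$pct_carbon), 100, tolerance = 1e-10)
  expect_equal(sum(grp$pct_water), 100, tolerance = 1e-10)
  # subgroups partition the totals too
  expect_equal(sum(tab$pct_carbon[tab$level == "subgroup"]), 100, tolerance = 1e-10)
  # total beef row exists and its ratio is coherent
  beef <- tab[tab$level == "total_beef", ]
  expect_equal(nrow(beef), 1L)
  expect_equal(beef$ratio_carbon, beef$pct_carbon / beef$pct_energy)
})

test_that("contribution pooling weights strata by expansion weight on per-capita values", {
  # two equal-weight strata with identical residents, carbon 100 (group 1)
  # and 300 (group 4): group 4 takes 75 % of the carbon footprint
  items <- tibble::tibble(
    item_code = c("C1", "C4"), name = c("a", "b"),
    nova_group = c(1L, 4L), subgroup = c("cereals", "snacks"),
    is_beef = FALSE, energy_density = 100, edible_fraction = 1,
    carbon_intensity = 100, water_intensity = 100
  )
  strata <- test_strata(2)
  purchases <- tibble::tibble(
    household_id = c("H1", "H2"),
    stratum_id = c("S01", "S02"),
    item_code = c("C1", "C4"),
    quantity = c(1, 3)
  )
  tab <- contribution_table(purchases, items, strata)
  expect_equal(tab$pct_carbon[tab$level == "group" & tab$nova_group == 4L], 75)
  # doubling one stratum's weight shifts the split accordingly: 100*1 vs 300*2
  strata$expansion_weight[2] <- 200
  tab <- contribution_table(purchases, items, strata)
  expect_equal(tab$pct_carbon[tab$level == "group" & tab$nova_group == 4L], 600 / 700 * 100)
})

test_that("contribution table fails on an empty or zero universe", {
  items <- test_items()
  strata <- test_strata(1)
  zero <- tibble::tibble(
    household_id = "H1", stratum_id = "S01", item_code = "A2", quantity = 0
  )
  expect_error(contribution_table(zero, items, strata), "positive")
})
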