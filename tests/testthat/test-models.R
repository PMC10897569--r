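# Weighted quintile regression, predictive margins, trend and interaction
# tests.

test_that("crude quintile contrasts recover group means on balanced toy data", {
  # 10 strata, exposures 1..10 -> quintile pairs; outcome deterministic by
  # quintile with means 100, 150, 200, 250, 300
  profiles <- test_strata(10)
  profiles$stratum_id <- sprintf("S%02d", 1:10)
  means <- c(100, 150, 200, 250, 300)
  summaries <- tibble::tibble(
    stratum_id = profiles$stratum_id,
    energy = 1000, carbon = 1, water = 1,
    pct_energy_upf = 15,
    pct_energy_beef = 1:10,
    carbon_per_1000kcal = rep(means, each = 2),
    water_per_1000kcal = rep(means, each = 2)
  )
  a <- assign_exposure_quintiles(summaries, profiles, "beef")
  fit <- fit_quintile_model(summaries, a, profiles, "carbon_per_1000kcal", "crude")
  expect_equal(unname(coef(fit$fit)[["quintile2"]]), 50)
  expect_equal(fit$adjusted_means$mean, means)
  expect_equal(fit$n_strata, 10L)
})

test_that("a constant outcome yields zero contrasts and zero trend slope", {
  d <- direct_data(n = 60, seed = 8, noise = 0)
  d$summaries$carbon_per_1000kcal <- 42
  a <- assign_exposure_quintiles(d$summaries, d$profiles, "beef")
  fit <- fit_quintile_model(d$summaries, a, d$profiles, "carbon_per_1000kcal", "crude")
  expect_equal(unname(coef(fit$fit)[-1]), rep(0, 4), tolerance = 1e-10)
  expect_equal(fit$adjusted_means$mean, rep(42, 5), tolerance = 1e-10)
  p <- trend_test(d$summaries, a, d$profiles, "carbon_per_1000kcal", "crude")
  expect_equal(attr(p, "estimate"), 0, tolerance = 1e-10)
})

test_that("weighted mean of predictive margins equals the weighted mean outcome", {
  # WLS-with-intercept identity, for crude and adjusted fits
  d <- direct_data(n = 150, seed = 12, effect_beef = 60, effect_upf = 10, noise = 40)
  a <- assign_exposure_quintiles(d$summaries, d$profiles, "beef")
  for (adj in c("crude", "adjusted")) {
    fit <- fit_quintile_model(d$summaries, a, d$profiles, "carbon_per_1000kcal", adj)
    md <- dplyr::inner_join(
      dplyr::inner_join(d$summaries, a, by = "stratum_id"),
      d$profiles,
      by = "stratum_id"
    )
    pq <- tapply(md$expansion_weight, md$quintile, sum) / sum(md$expansion_weight)
    expect_equal(
      sum(pq * fit$adjusted_means$mean),
      stats::weighted.mean(md$carbon_per_1000kcal, md$expansion_weight),
      tolerance = 1e-10
    )
  }
})

test_that("rank deficiency is reported with the collinear term", {
  d <- direct_data(n = 60, seed = 3)
  # make the out-of-home share an exact linear function of income
  d$profiles$out_of_home_share <- d$profiles$income / 100
  a <- assign_exposure_quintiles(d$summaries, d$profiles, "beef")
  expect_error(
    fit_quintile_model(d$summaries, a, d$profiles, "carbon_per_1000kcal", "adjusted"),
    "rank deficient.*out_of_home_share"
  )
})

test_that("trend test detects a monotone effect and stays null under none", {
  up <- direct_data(n = 120, seed = 5, effect_beef = 80, noise = 10)
  a <- assign_exposure_quintiles(up$summaries, up$profiles, "beef")
  p <- trend_test(up$summaries, a, up$profiles, "carbon_per_1000kcal", "crude")
  expect_lt(as.numeric(p), 0.01)
  expect_gt(attr(p, "estimate"), 0)

  null <- direct_data(n = 120, seed = 6, effect_beef = 0, noise = 30)
  a0 <- assign_exposure_quintiles(null$summaries, null$profiles, "beef")
  p0 <- trend_test(null$summaries, a0, null$profiles, "carbon_per_1000kcal", "crude")
  expect_gt(as.numeric(p0), 0.01)
})

test_that("crude and adjusted estimates coincide when covariates are independent of exposure and outcome", {
  d <- direct_data(n = 600, seed = 17, effect_beef = 60, noise = 25)
  a <- assign_exposure_quintiles(d$summaries, d$profiles, "beef")
  crude <- fit_quintile_model(d$summaries, a, d$profiles, "carbon_per_1000kcal", "crude")
  adj <- fit_quintile_model(d$summaries, a, d$profiles, "carbon_per_1000kcal", "adjusted")
  # contrasts agree within a couple of robust standard errors
  for (q in 2:5) {
    term <- paste0("quintile", q)
    expect_lt(
      abs(coef(crude$fit)[[term]] - coef(adj$fit)[[term]]),
      2 * sqrt(crude$vcov[term, term])
    )
  }
})

test_that("fit_exposure_slope recovers a known linear dose-response", {
  d <- direct_data(n = 300, seed = 19, effect_beef = 75, effect_upf = 8, noise = 20)
  sl <- fit_exposure_slope(d$summaries, d$profiles, "beef", "carbon_per_1000kcal")
  expect_true(sl$conf_low < 75 && 75 < sl$conf_high)
  sl_u <- fit_exposure_slope(d$summaries, d$profiles, "upf", "carbon_per_1000kcal")
  expect_true(sl_u$conf_low < 8 && 8 < sl_u$conf_high)
})

test_that("interaction Wald test has 16 df, accepts additive data and rejects a strong product term", {
  add <- direct_data(n = 400, seed = 23, effect_beef = 60, effect_upf = 8, noise = 25)
  aa <- both_assignments(add$summaries, add$profiles)
  p_add <- interaction_wald(
    add$summaries, aa$beef, aa$upf, add$profiles, "carbon_per_1000kcal"
  )
  expect_equal(attr(p_add, "df"), 16L)
  expect_gt(as.numeric(p_add), 0.05)

  prod <- direct_data(
    n = 400, seed = 24, effect_beef = 60, effect_upf = 8,
    effect_interaction = 25, noise = 25
  )
  pp <- both_assignments(prod$summaries, prod$profiles)
  p_prod <- interaction_wald(
    prod$summaries, pp$beef, pp$upf, prod$profiles, "carbon_per_1000kcal"
  )
  expect_lt(as.numeric(p_prod), 0.01)
})
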