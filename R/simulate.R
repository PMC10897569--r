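# Synthetic household-budget-survey generator.
#
# Generation is energy-share-first: each stratum draws target percentages of
# energy from beef and from ultra-processed foods, allocates the remaining
# energy across the other items by a symmetric random composition, and only
# then inverts energy to as-purchased masses through each item's energy
# density and edible fraction. Ground truth is therefore exact in the space
# the analysis works in (% energy and per-1000-kcal intensities).
#
# Beef energy is split across the three beef subgroups with fixed proportions
# (fresh cuts dominate); the group-4 portion counts towards the UPF exposure,
# so the non-beef UPF allocation is the UPF target minus that portion.

.beef_group_split <- c("1" = 0.75, "3" = 0.10, "4" = 0.15)

#' Configuration for the synthetic household-budget-survey generator
#'
#' Bundles and validates every knob of the generator. All randomness flows
#' from `seed`; the same configuration always reproduces the same tables.
#'
#' @param seed Integer seed.
#' @param n_strata Number of sampling strata (default 120 -- enough for
#'   clean quintile granularity while keeping simulation studies fast).
#' @param households_range Integer range of households per stratum (default
#'   16--120).
#' @param n_items Number of food items in the reference (default 40; at least
#'   12 so every Nova group has two items besides the three beef items placed
#'   in groups 1, 3 and 4).
#' @param beef_share_range,upf_share_range Ranges (% of energy) from which
#'   each stratum's beef and ultra-processed-food energy-share targets are
#'   drawn uniformly; defaults span the quintile spreads observed in national
#'   household-budget data (beef 3--8.2 %, UPF 10.1--28.1 %).
#' @param beef_carbon_multiplier,beef_water_multiplier Ratio of beef item
#'   footprint intensity to the mean non-beef intensity (defaults 15 and 10,
#'   chosen so beef's footprint/energy ratios land near the magnitudes seen in
#'   national accounting, i.e. roughly 9 for carbon and 7 for water at a ~5 %
#'   beef energy share).
#' @param noise_sd Standard deviation of the multiplicative log-normal noise
#'   applied to as-purchased quantities (default 0.05; 0 gives exact
#'   inversion of the energy targets).
#' @param energy_mean,energy_sd Mean and sd (kcal/person-day) of each
#'   stratum's at-home dietary energy availability (defaults 1200 and 120,
#'   the order of magnitude seen for household food purchases excluding
#'   out-of-home consumption).
#' @param covariate_effects Optional named list of confounding strengths:
#'   `beef_income` and/or `upf_income` shift the exposure targets by that many
#'   percentage points per standard deviation of log income.
#' @return A validated list of class `hbs_sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_strata = 120L,
                              households_range = c(16L, 120L),
                              n_items = 40L,
                              beef_share_range = c(3.0, 8.2),
                              upf_share_range = c(10.1, 28.1),
                              beef_carbon_multiplier = 15,
                              beef_water_multiplier = 10,
                              noise_sd = 0.05,
                              energy_mean = 1200,
                              energy_sd = 120,
                              covariate_effects = NULL) {
  stopifnot(
    length(seed) == 1, is.finite(seed),
    length(n_strata) == 1, n_strata >= 5,
    length(households_range) == 2, all(households_range >= 1),
    households_range[1] <= households_range[2],
    length(n_items) == 1, n_items >= 12,
    length(beef_share_range) == 2, length(upf_share_range) == 2,
    all(beef_share_range >= 0), all(beef_share_range <= 100),
    all(upf_share_range >= 0), all(upf_share_range <= 100),
    beef_share_range[1] <= beef_share_range[2],
    upf_share_range[1] <= upf_share_range[2],
    beef_carbon_multiplier > 0, beef_water_multiplier > 0,
    noise_sd >= 0, energy_mean > 0, energy_sd >= 0
  )
  if (!is.null(covariate_effects)) {
    stopifnot(
      is.list(covariate_effects),
      all(names(covariate_effects) %in% c("beef_income", "upf_income"))
    )
  }
  structure(
    list(
      seed = as.integer(seed),
      n_strata = as.integer(n_strata),
      households_range = as.integer(households_range),
      n_items = as.integer(n_items),
      beef_share_range = as.numeric(beef_share_range),
      upf_share_range = as.numeric(upf_share_range),
      beef_carbon_multiplier = beef_carbon_multiplier,
      beef_water_multiplier = beef_water_multiplier,
      noise_sd = noise_sd,
      energy_mean = energy_mean,
      energy_sd = energy_sd,
      covariate_effects = covariate_effects
    ),
    class = "hbs_sim_config"
  )
}

#' Read a simulation configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of
#'   [simulation_config()].
#' @return An `hbs_sim_config` object.
#' @export
read_simulation_config <- function(path) {
  do.call(simulation_config, yaml::read_yaml(path))
}

#' Generate a synthetic food reference table
#'
#' Builds `n_items` food items: three beef items (fresh cuts in Nova group 1,
#' salted/cured/smoked in group 3, reconstituted products in group 4) and
#' non-beef items spread across all four groups. Energy densities and edible
#' fractions are drawn from group-typical ranges. Non-beef footprint
#' intensities are log-normal, except Nova group 2 (culinary ingredients)
#' whose intensities are near zero; every beef item receives exactly
#' `beef_carbon_multiplier` (resp. `beef_water_multiplier`) times the mean
#' non-beef intensity.
#'
#' @param config An `hbs_sim_config` (see [simulation_config()]).
#' @return A validated food reference tibble.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "hbs_sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_items
    rem <- n - 3L
    g2 <- max(2L, round(0.15 * rem))
    g3 <- max(2L, round(0.20 * rem))
    g4 <- max(2L, round(0.25 * rem))
    g1 <- rem - g2 - g3 - g4
    if (g1 < 2L) stop("n_items too small to place two items in every Nova group", call. = FALSE)

    nb_group <- c(rep(1L, g1), rep(2L, g2), rep(3L, g3), rep(4L, g4))
    nb_sub <- character(rem)
    pools <- list(
      "1" = c("cereals and beans", "fruits", "vegetables and roots", "milk", "poultry and eggs", "fish"),
      "2" = c("oils and fats", "table sugar", "salt and vinegar"),
      "3" = c("breads", "cheeses", "canned vegetables"),
      "4" = c("soft drinks", "cookies and cakes", "ready meals", "processed snacks", "margarines")
    )
    for (g in 1:4) {
      idx <- which(nb_group == g)
      nb_sub[idx] <- sample(pools[[as.character(g)]], length(idx), replace = TRUE)
    }
    nb_ed <- numeric(rem)
    nb_ed[nb_group == 1L] <- runif(g1, 30, 350)
    nb_ed[nb_group == 2L] <- runif(g2, 350, 900)
    nb_ed[nb_group == 3L] <- runif(g3, 150, 450)
    nb_ed[nb_group == 4L] <- runif(g4, 250, 550)
    nb_ef <- ifelse(nb_group == 1L, runif(rem, 0.6, 1), runif(rem, 0.9, 1))
    # intensity scales differ by group so that per-kcal intensities order
    # beef >> ultra-processed > unprocessed/processed > culinary ingredients,
    # the gradient observed in national footprint accounting (culinary
    # ingredients near zero, ultra-processed mildly above the diet average)
    nb_carbon <- dplyr::case_when(
      nb_group == 2L ~ runif(rem, 20, 120),
      nb_group == 4L ~ rlnorm(rem, log(4100), 0.35),
      TRUE ~ rlnorm(rem, log(1400), 0.4)
    )
    nb_water <- dplyr::case_when(
      nb_group == 2L ~ runif(rem, 20, 150),
      nb_group == 4L ~ rlnorm(rem, log(3800), 0.35),
      TRUE ~ rlnorm(rem, log(1300), 0.4)
    )

    beef_carbon <- config$beef_carbon_multiplier * mean(nb_carbon)
    beef_water <- config$beef_water_multiplier * mean(nb_water)
    beef <- tibble(
      nova_group = c(1L, 3L, 4L),
      subgroup = c("beef", "salted, cured, smoked beef", "reconstituted beef products"),
      is_beef = TRUE,
      energy_density = c(runif(1, 120, 250), runif(1, 150, 300), runif(1, 200, 300)),
      edible_fraction = runif(3, 0.7, 0.95),
      carbon_intensity = beef_carbon,
      water_intensity = beef_water
    )
    nonbeef <- tibble(
      nova_group = nb_group,
      subgroup = nb_sub,
      is_beef = FALSE,
      energy_density = nb_ed,
      edible_fraction = nb_ef,
      carbon_intensity = nb_carbon,
      water_intensity = nb_water
    )
    ref <- bind_rows(beef, nonbeef) %>%
      arrange(.data$nova_group, dplyr::desc(.data$is_beef), .data$subgroup) %>%
      mutate(
        item_code = sprintf("F%03d", dplyr::row_number()),
        name = sprintf("%s item %d", .data$subgroup, dplyr::row_number()),
        .before = 1
      )
    validate_food_reference(ref[, names(.ref_csv_cols)])
  })
}

# Per-kcal footprint intensity of each item: intensity per as-purchased kg
# divided by kcal per as-purchased kg (edible_fraction * 10 * energy_density).
.per_kcal_intensity <- function(ref, col) {
  ref[[col]] / (ref$edible_fraction * 10 * ref$energy_density)
}

# Expected per-kcal intensities of the three allocation categories, using the
# expected (symmetric-Dirichlet, i.e. equal) within-category weights.
.category_intensities <- function(ref, col) {
  k <- .per_kcal_intensity(ref, col)
  beef_groups <- intersect(names(.beef_group_split), as.character(unique(ref$nova_group[ref$is_beef])))
  split <- .beef_group_split[beef_groups] / sum(.beef_group_split[beef_groups])
  k_beef <- sum(vapply(beef_groups, function(g) {
    split[[g]] * mean(k[ref$is_beef & ref$nova_group == as.integer(g)])
  }, numeric(1)))
  k_upf <- mean(k[!ref$is_beef & ref$nova_group == 4L])
  k_other <- mean(k[!ref$is_beef & ref$nova_group != 4L])
  list(beef = k_beef, upf = k_upf, other = k_other)
}

#' Generate a synthetic survey population with known ground truth
#'
#' For each stratum: draws household counts and sizes, covariates and an
#' expansion weight; draws beef and ultra-processed energy-share targets from
#' their configured ranges (optionally shifted by log income when
#' `covariate_effects` is set); allocates the stratum's total 7-day energy to
#' items (beef energy split across the beef subgroups with fixed proportions,
#' symmetric Dirichlet compositions within categories); inverts item energies
#' to as-purchased masses via energy density and edible fraction; applies
#' mean-one multiplicative log-normal quantity noise; and splits each item's
#' mass across households proportionally to household size.
#'
#' The returned `ground_truth` holds each stratum's target exposure shares
#' and its exact (pre-noise) per-1000-kcal carbon and water intensities, plus
#' the closed-form slopes of expected intensity per percentage point of each
#' exposure implied by the category intensities (see [expected_results()]).
#'
#' @param config An `hbs_sim_config`.
#' @param reference A food reference generated by [generate_reference()] (or
#'   any table with the same structure).
#' @return A list with elements `purchases`, `strata` and `ground_truth`
#'   (itself a list: `per_stratum` tibble and `slopes` tibble).
#' @export
generate_population <- function(config, reference) {
  stopifnot(inherits(config, "hbs_sim_config"))
  ref <- validate_food_reference(reference)
  withr::with_seed(config$seed, {
    n <- config$n_strata
    hr <- config$households_range
    nh <- sample(seq(hr[1], hr[2]), n, replace = TRUE)
    sizes <- lapply(nh, function(k) {
      sample(1:6, k, replace = TRUE, prob = c(0.15, 0.25, 0.25, 0.2, 0.1, 0.05))
    })
    n_res <- vapply(sizes, sum, integer(1))
    strata <- tibble(
      stratum_id = sprintf("S%04d", seq_len(n)),
      n_households = nh,
      n_residents = n_res,
      expansion_weight = rlnorm(n, log(5e4), 0.6),
      income = rlnorm(n, log(2000), 0.5),
      area = sample(.df_areas, n, replace = TRUE, prob = c(0.8, 0.2)),
      region = sample(.df_regions, n, replace = TRUE),
      out_of_home_share = runif(n, 5, 40)
    )

    b <- runif(n, config$beef_share_range[1], config$beef_share_range[2])
    u <- runif(n, config$upf_share_range[1], config$upf_share_range[2])
    ce <- config$covariate_effects
    if (!is.null(ce)) {
      z <- as.numeric(scale(log(strata$income)))
      if (!is.null(ce$beef_income)) b <- pmin(pmax(b + ce$beef_income * z, 0.1), 95)
      if (!is.null(ce$upf_income)) u <- pmin(pmax(u + ce$upf_income * z, 0.1), 95)
    }

    beef_groups <- as.character(sort(unique(ref$nova_group[ref$is_beef])))
    split <- .beef_group_split[intersect(names(.beef_group_split), beef_groups)]
    split <- split / sum(split)
    f4 <- if ("4" %in% names(split)) split[["4"]] else 0
    u_nb <- u - f4 * b
    if (any(u_nb <= 0) || any(b + u_nb >= 100)) {
      stop("infeasible share targets: beef and ultra-processed energy shares cannot both be met", call. = FALSE)
    }

    idx_beef <- lapply(names(split), function(g) which(ref$is_beef & ref$nova_group == as.integer(g)))
    names(idx_beef) <- names(split)
    idx_upf <- which(!ref$is_beef & ref$nova_group == 4L)
    idx_other <- which(!ref$is_beef & ref$nova_group != 4L)
    if (length(idx_upf) == 0 || length(idx_other) == 0) {
      stop("reference must contain non-beef ultra-processed items and non-beef items outside group 4", call. = FALSE)
    }
    k_carbon <- .per_kcal_intensity(ref, "carbon_intensity")
    k_water <- .per_kcal_intensity(ref, "water_intensity")
    mass_per_kcal <- 1 / (ref$edible_fraction * 10 * ref$energy_density)

    energy_pc <- pmax(rnorm(n, config$energy_mean, config$energy_sd), 200)
    rdirichlet <- function(k, shape = 2) {
      g <- rgamma(k, shape = shape)
      g / sum(g)
    }

    purchases_list <- vector("list", n)
    gt_carbon <- gt_water <- numeric(n)
    for (s in seq_len(n)) {
      sh <- numeric(nrow(ref))
      for (g in names(split)) {
        ii <- idx_beef[[g]]
        sh[ii] <- (b[s] / 100) * split[[g]] * rdirichlet(length(ii))
      }
      sh[idx_upf] <- (u_nb[s] / 100) * rdirichlet(length(idx_upf))
      sh[idx_other] <- (1 - b[s] / 100 - u_nb[s] / 100) * rdirichlet(length(idx_other))

      e_total <- energy_pc[s] * 7 * n_res[s]
      e_items <- sh * e_total
      mass <- e_items * mass_per_kcal
      if (config$noise_sd > 0) {
        mass <- mass * exp(rnorm(length(mass), 0, config$noise_sd) - config$noise_sd^2 / 2)
      }
      gt_carbon[s] <- 1000 * sum(sh * k_carbon)
      gt_water[s] <- 1000 * sum(sh * k_water)

      hw <- rgamma(nh[s], shape = sizes[[s]])
      hw <- hw / sum(hw)
      purchases_list[[s]] <- tibble(
        household_id = rep(sprintf("%s_H%03d", strata$stratum_id[s], seq_len(nh[s])), each = nrow(ref)),
        stratum_id = strata$stratum_id[s],
        item_code = rep(ref$item_code, times = nh[s]),
        quantity = as.vector(outer(mass, hw))
      )
    }
    purchases <- bind_rows(purchases_list)

    kc <- .category_intensities(ref, "carbon_intensity")
    kw <- .category_intensities(ref, "water_intensity")
    slopes <- tibble(
      outcome = rep(c("carbon_per_1000kcal", "water_per_1000kcal"), each = 2),
      exposure = rep(c("beef", "upf"), 2),
      slope = c(
        10 * (kc$beef - f4 * kc$upf - (1 - f4) * kc$other),
        10 * (kc$upf - kc$other),
        10 * (kw$beef - f4 * kw$upf - (1 - f4) * kw$other),
        10 * (kw$upf - kw$other)
      )
    )
    list(
      purchases = purchases,
      strata = strata,
      ground_truth = list(
        per_stratum = tibble(
          stratum_id = strata$stratum_id,
          pct_energy_beef = b,
          pct_energy_upf = u,
          energy_per_capita = energy_pc,
          carbon_per_1000kcal = gt_carbon,
          water_per_1000kcal = gt_water
        ),
        slopes = slopes
      )
    )
  })
}

#' Recompute the ground truth implied by a simulation configuration
#'
#' Deterministically regenerates the reference and population for `config`
#' (same seed, same draws) and returns only the ground truth: per-stratum
#' target exposure shares, exact pre-noise per-1000-kcal intensities, and the
#' closed-form expected intensity slopes per percentage point of each
#' exposure.
#'
#' @param config An `hbs_sim_config`.
#' @return The `ground_truth` list (see [generate_population()]).
#' @export
expected_results <- function(config) {
  generate_population(config, generate_reference(config))$ground_truth
}

#' Write a complete synthetic survey to disk
#'
#' Generates the reference, purchases and strata for `config` and writes them
#' as the three canonical CSV inputs plus `ground_truth.json`.
#'
#' @param config An `hbs_sim_config`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named list of the four file paths.
#' @export
run_simulation <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ref <- generate_reference(config)
  pop <- generate_population(config, ref)
  paths <- list(
    reference = file.path(outdir, "food_reference.csv"),
    purchases = file.path(outdir, "purchases.csv"),
    strata = file.path(outdir, "strata.csv"),
    ground_truth = file.path(outdir, "ground_truth.json")
  )
  write_food_reference(ref, paths$reference)
  write_purchases(pop$purchases, paths$purchases)
  write_strata(pop$strata, paths$strata)
  jsonlite::write_json(
    list(
      per_stratum = pop$ground_truth$per_stratum,
      slopes = pop$ground_truth$slopes
    ),
    paths$ground_truth,
    digits = NA, auto_unbox = TRUE
  )
  message(sprintf(
    "simulated %d strata, %d purchase records, %d food items -> %s",
    nrow(pop$strata), nrow(pop$purchases), nrow(ref), outdir
  ))
  invisible(paths)
}
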