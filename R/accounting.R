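# Footprint accounting: purchases -> per-capita daily energy and footprints.
#
# Energy is computed on the edible portion only (quantity x edible_fraction,
# converted through the kcal/100 g energy density); carbon and water
# footprints apply the per-kg intensity to the FULL as-purchased mass, because
# discarded parts (husks, seeds, bones) are inherent to producing the edible
# fraction. Cooking-stage impacts are out of scope.

#' Dietary energy of a purchased quantity
#'
#' `quantity_kg * edible_fraction * 1000 / 100 * energy_density`: the edible
#' mass in units of 100 g times the energy density of the edible portion.
#'
#' @param quantity_kg As-purchased quantity in kg (or litres), non-negative.
#'   Vectorised; recycled against `item` rows.
#' @param item One or more rows of a food reference table.
#' @return Energy in kcal.
#' @export
item_energy <- function(quantity_kg, item) {
  if (any(quantity_kg < 0, na.rm = TRUE)) {
    stop("quantity_kg must be >= 0", call. = FALSE)
  }
  quantity_kg * item$edible_fraction * 10 * item$energy_density
}

#' Carbon and water footprints of a purchased quantity
#'
#' Footprint intensities are cradle-to-retail coefficients per as-purchased kg,
#' so the full purchased mass is used -- the edible fraction is deliberately
#' NOT applied (halving the edible fraction halves the energy but leaves both
#' footprints unchanged).
#'
#' @inheritParams item_energy
#' @return A tibble with columns `carbon_g` (gCO2eq) and `water_l` (litres).
#' @export
item_footprints <- function(quantity_kg, item) {
  if (any(quantity_kg < 0, na.rm = TRUE)) {
    stop("quantity_kg must be >= 0", call. = FALSE)
  }
  tibble(
    carbon_g = quantity_kg * item$carbon_intensity,
    water_l = quantity_kg * item$water_intensity
  )
}

#' Convert a 7-day stratum total to a per-capita daily value
#'
#' @param total_7day Any additive quantity accumulated over the 7-day diary.
#' @param n_residents Total residents of the stratum (>= 1).
#' @return `total_7day / 7 / n_residents`.
#' @export
per_capita_daily <- function(total_7day, n_residents) {
  if (any(n_residents < 1, na.rm = TRUE)) {
    stop("n_residents must be >= 1", call. = FALSE)
  }
  total_7day / 7 / n_residents
}

# Join purchases to the reference and attach per-record energy/footprints.
.purchase_records <- function(purchases, items) {
  unknown <- setdiff(unique(purchases$item_code), items$item_code)
  if (length(unknown) > 0) {
    stop(sprintf(
      "purchases contain item code(s) absent from the food reference: %s",
      paste(head(unknown, 5L), collapse = ", ")
    ), call. = FALSE)
  }
  purchases %>%
    inner_join(
      items %>%
        select("item_code", "nova_group", "subgroup", "is_beef",
               "energy_density", "edible_fraction",
               "carbon_intensity", "water_intensity"),
      by = "item_code"
    ) %>%
    mutate(
      energy_kcal = .data$quantity * .data$edible_fraction * 10 * .data$energy_density,
      carbon_g = .data$quantity * .data$carbon_intensity,
      water_l = .data$quantity * .data$water_intensity
    )
}

#' Summarise purchases into per-capita daily diet summaries by stratum
#'
#' For every stratum in `profiles`, sums item-level energy (edible portion)
#' and carbon/water footprints (full purchased mass) over the 7-day diary,
#' converts to per-capita daily values, and derives the two exposure shares --
#' percentage of energy from ultra-processed foods (Nova group 4) and from
#' beef items (across Nova groups 1, 3 and 4) -- and the energy-standardised
#' footprint intensities per 1000 kcal.
#'
#' Strata with zero total energy have undefined shares and intensities; those
#' fields are set to `NA` and a warning reports the count (such strata are
#' excluded from the regression models).
#'
#' @param purchases Purchase table (see [read_purchases()]).
#' @param items Food reference table.
#' @param profiles Stratum attribute table (see [read_strata()]); strata with
#'   no purchase records receive zero totals.
#' @return A tibble with one row per stratum: `stratum_id`, `energy`
#'   (kcal/person-day), `carbon` (gCO2eq/person-day), `water` (l/person-day),
#'   `pct_energy_upf`, `pct_energy_beef` (% of energy), `carbon_per_1000kcal`,
#'   `water_per_1000kcal`.
#' @export
summarise_strata <- function(purchases, items, profiles) {
  rec <- .purchase_records(purchases, items)
  extra <- setdiff(unique(rec$stratum_id), profiles$stratum_id)
  if (length(extra) > 0) {
    stop(sprintf(
      "purchases reference stratum id(s) absent from the stratum table: %s",
      paste(head(extra, 5L), collapse = ", ")
    ), call. = FALSE)
  }
  agg <- rec %>%
    group_by(.data$stratum_id) %>%
    summarise(
      energy_tot = sum(.data$energy_kcal),
      carbon_tot = sum(.data$carbon_g),
      water_tot = sum(.data$water_l),
      beef_energy = sum(.data$energy_kcal[.data$is_beef]),
      upf_energy = sum(.data$energy_kcal[.data$nova_group == 4L]),
      .groups = "drop"
    )
  out <- profiles %>%
    select("stratum_id", "n_residents") %>%
    left_join(agg, by = "stratum_id") %>%
    mutate(across(
      c("energy_tot", "carbon_tot", "water_tot", "beef_energy", "upf_energy"),
      ~ dplyr::coalesce(.x, 0)
    )) %>%
    mutate(
      energy = per_capita_daily(.data$energy_tot, .data$n_residents),
      carbon = per_capita_daily(.data$carbon_tot, .data$n_residents),
      water = per_capita_daily(.data$water_tot, .data$n_residents),
      pct_energy_upf = ifelse(.data$energy_tot > 0,
        .data$upf_energy / .data$energy_tot * 100, NA_real_
      ),
      pct_energy_beef = ifelse(.data$energy_tot > 0,
        .data$beef_energy / .data$energy_tot * 100, NA_real_
      ),
      carbon_per_1000kcal = ifelse(.data$energy_tot > 0,
        .data$carbon_tot / .data$energy_tot * 1000, NA_real_
      ),
      water_per_1000kcal = ifelse(.data$energy_tot > 0,
        .data$water_tot / .data$energy_tot * 1000, NA_real_
      )
    ) %>%
    select(
      "stratum_id", "energy", "carbon", "water",
      "pct_energy_upf", "pct_energy_beef",
      "carbon_per_1000kcal", "water_per_1000kcal"
    )
  n_zero <- sum(is.na(out$carbon_per_1000kcal))
  if (n_zero > 0) {
    warning(sprintf(
      "%d stratum(s) with zero total energy: exposure shares and per-1000-kcal intensities set to NA",
      n_zero
    ), call. = FALSE)
  }
  out
}

#' @rdname summarise_strata
#' @param profile A single-row stratum profile; purchases are filtered to that
#'   stratum.
#' @export
summarise_stratum <- function(purchases, items, profile) {
  if (nrow(profile) != 1) {
    stop("profile must be a single stratum row", call. = FALSE)
  }
  summarise_strata(
    purchases[purchases$stratum_id == profile$stratum_id, , drop = FALSE],
    items, profile
  )
}

#' Ratio of footprint share to energy share
#'
#' A food group's percentage share of the total carbon (or water) footprint
#' divided by its percentage share of dietary energy. A ratio of 1 marks a
#' group whose footprint is proportional to the calories it supplies; above 1,
#' a disproportionately impactful group. Undefined (NA) when the energy share
#' is zero.
#'
#' @param pct_footprint Footprint share in percent.
#' @param pct_energy Energy share in percent.
#' @return The unitless ratio, vectorised; full precision (round at reporting
#'   time).
#' @export
footprint_energy_ratio <- function(pct_footprint, pct_energy) {
  if (any(pct_energy < 0, na.rm = TRUE) || any(pct_footprint < 0, na.rm = TRUE)) {
    stop("percentage shares must be >= 0", call. = FALSE)
  }
  ifelse(pct_energy > 0, pct_footprint / pct_energy, NA_real_)
}

#' Nova-group contribution table with footprint/energy ratios
#'
#' Pools expansion-weight-weighted per-capita purchases across strata and
#' computes, for each Nova group, each subgroup and for beef as a whole
#' (pooled across Nova groups 1, 3 and 4), its percentage contribution to
#' total energy, carbon footprint and water footprint, together with the
#' footprint/energy ratios.
#'
#' @inheritParams summarise_strata
#' @return A tibble with columns `label`, `level` (`"group"`, `"subgroup"` or
#'   `"total_beef"`), `nova_group`, `pct_energy`, `pct_carbon`, `pct_water`,
#'   `ratio_carbon`, `ratio_water`. Within the four Nova groups each `pct_`
#'   column sums to 100.
#' @export
contribution_table <- function(purchases, items, profiles) {
  rec <- .purchase_records(purchases, items) %>%
    inner_join(
      profiles %>% select("stratum_id", "n_residents", "expansion_weight"),
      by = "stratum_id"
    ) %>%
    mutate(
      w_energy = .data$expansion_weight * per_capita_daily(.data$energy_kcal, .data$n_residents),
      w_carbon = .data$expansion_weight * per_capita_daily(.data$carbon_g, .data$n_residents),
      w_water = .data$expansion_weight * per_capita_daily(.data$water_l, .data$n_residents)
    )
  grand <- rec %>%
    summarise(
      energy = sum(.data$w_energy),
      carbon = sum(.data$w_carbon),
      water = sum(.data$w_water)
    )
  if (grand$energy <= 0 || grand$carbon <= 0 || grand$water <= 0) {
    stop("grand totals of energy, carbon and water must all be positive", call. = FALSE)
  }
  pool <- function(df, label, level, nova = NA_integer_) {
    df %>%
      summarise(
        pct_energy = sum(.data$w_energy) / grand$energy * 100,
        pct_carbon = sum(.data$w_carbon) / grand$carbon * 100,
        pct_water = sum(.data$w_water) / grand$water * 100,
        .groups = "drop"
      ) %>%
      mutate(label = label, level = level, nova_group = nova, .before = 1)
  }
  groups <- lapply(1:4, function(g) {
    pool(rec %>% filter(.data$nova_group == g),
      label = unname(.df_nova_labels[as.character(g)]),
      level = "group", nova = g
    )
  })
  subgroups <- rec %>%
    group_by(.data$nova_group, .data$subgroup) %>%
    summarise(
      pct_energy = sum(.data$w_energy) / grand$energy * 100,
      pct_carbon = sum(.data$w_carbon) / grand$carbon * 100,
      pct_water = sum(.data$w_water) / grand$water * 100,
      .groups = "drop"
    ) %>%
    arrange(.data$nova_group, .data$subgroup) %>%
    mutate(label = .data$subgroup, level = "subgroup") %>%
    select("label", "level", "nova_group", "pct_energy", "pct_carbon", "pct_water")
  beef <- pool(rec %>% filter(.data$is_beef), label = "total beef", level = "total_beef")
  bind_rows(bind_rows(groups), subgroups, beef) %>%
    mutate(
      ratio_carbon = footprint_energy_ratio(.data$pct_carbon, .data$pct_energy),
      ratio_water = footprint_energy_ratio(.data$pct_water, .data$pct_energy)
    )
}
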