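# Input tables: a food reference (composition + footprint coefficients), a
# 7-day purchase diary and a stratum attribute table. CSV headers are fixed;
# internally the package uses shorter column names (the mapping below).

.ref_csv_cols <- c(
  item_code = "item_code",
  name = "name",
  nova_group = "nova_group",
  subgroup = "subgroup",
  is_beef = "is_beef",
  energy_density = "energy_density_kcal_per_100g_edible",
  edible_fraction = "edible_fraction",
  carbon_intensity = "carbon_intensity_gco2eq_per_kg",
  water_intensity = "water_intensity_l_per_kg"
)

.purchases_csv_cols <- c(
  household_id = "household_id",
  stratum_id = "stratum_id",
  item_code = "item_code",
  quantity = "quantity_kg_7day"
)

.strata_csv_cols <- c(
  stratum_id = "stratum_id",
  n_households = "n_households",
  n_residents = "n_residents",
  expansion_weight = "expansion_weight",
  income = "income",
  area = "area",
  region = "region",
  out_of_home_share = "out_of_home_share_pct"
)

.read_table <- function(path, col_map, col_types, label) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: '%s'", label, path), call. = FALSE)
  }
  df <- readr::read_csv(path, col_types = col_types, progress = FALSE)
  missing <- setdiff(unname(col_map), names(df))
  if (length(missing) > 0) {
    stop(sprintf(
      "%s file '%s' is missing required column(s): %s",
      label, path, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop(sprintf(
      "%s file '%s' could not be parsed cleanly (first issue: row %d, column %d: expected %s)",
      label, path, probs$row[1], probs$col[1], probs$expected[1]
    ), call. = FALSE)
  }
  df <- df[, unname(col_map)]
  names(df) <- names(col_map)
  as_tibble(df)
}

.collect_errors <- function(errors, label) {
  if (length(errors) > 0) {
    shown <- head(errors, 20L)
    if (length(errors) > length(shown)) {
      shown <- c(shown, sprintf("... and %d more", length(errors) - length(shown)))
    }
    stop(sprintf("invalid %s:\n  %s", label, paste(shown, collapse = "\n  ")),
      call. = FALSE
    )
  }
  invisible(NULL)
}

#' Validate a food reference table
#'
#' Checks every row of an in-memory food reference table against the data
#' model: Nova group in 1--4, non-negative energy density and footprint
#' intensities, edible fraction in (0, 1], unique item codes, and no beef item
#' placed in Nova group 2 (beef occurs as fresh cuts in group 1, salted/cured/
#' smoked products in group 3 and reconstituted products in group 4, never as a
#' culinary ingredient).
#'
#' @param ref A data frame with columns `item_code`, `name`, `nova_group`,
#'   `subgroup`, `is_beef`, `energy_density`, `edible_fraction`,
#'   `carbon_intensity`, `water_intensity`.
#' @return The validated table as a tibble, invisibly unchanged. Errors name
#'   the offending row, item and field.
#' @export
validate_food_reference <- function(ref) {
  ref <- as_tibble(ref)
  errors <- character()
  say <- function(idx, msg) {
    sprintf("row %d (item '%s'): %s", idx, as.character(ref$item_code[idx]), msg)
  }
  dup <- duplicated(ref$item_code)
  for (i in which(dup)) errors <- c(errors, say(i, "duplicate item_code"))
  for (i in seq_len(nrow(ref))) {
    r <- ref[i, ]
    if (is.na(r$item_code) || !nzchar(r$item_code)) {
      errors <- c(errors, sprintf("row %d: empty item_code", i))
      next
    }
    if (is.na(r$nova_group) || !(r$nova_group %in% 1:4)) {
      errors <- c(errors, say(i, sprintf("nova_group must be 1, 2, 3 or 4, got %s", r$nova_group)))
    }
    if (is.na(r$is_beef)) {
      errors <- c(errors, say(i, "is_beef must be TRUE or FALSE"))
    } else if (isTRUE(r$is_beef) && identical(as.integer(r$nova_group), 2L)) {
      errors <- c(errors, say(i, "is_beef items cannot be in nova_group 2 (beef occurs in groups 1, 3 and 4 only)"))
    }
    if (is.na(r$energy_density) || r$energy_density < 0) {
      errors <- c(errors, say(i, sprintf("energy_density must be >= 0, got %s", r$energy_density)))
    }
    if (is.na(r$edible_fraction) || r$edible_fraction <= 0 || r$edible_fraction > 1) {
      errors <- c(errors, say(i, sprintf("edible_fraction must be in (0, 1], got %s", r$edible_fraction)))
    }
    if (is.na(r$carbon_intensity) || r$carbon_intensity < 0) {
      errors <- c(errors, say(i, sprintf("carbon_intensity must be >= 0, got %s", r$carbon_intensity)))
    }
    if (is.na(r$water_intensity) || r$water_intensity < 0) {
      errors <- c(errors, say(i, sprintf("water_intensity must be >= 0, got %s", r$water_intensity)))
    }
  }
  .collect_errors(errors, "food reference")
  ref$nova_group <- as.integer(ref$nova_group)
  ref$is_beef <- as.logical(ref$is_beef)
  ref
}

#' Read a food reference table from CSV
#'
#' The reference table carries, for each purchasable food item, its Nova
#' processing group and subgroup, a beef flag, the energy density of the edible
#' portion (kcal per 100 g), the edible fraction of the as-purchased mass, and
#' cradle-to-retail carbon (gCO2eq/kg) and water (l/kg) footprint intensities
#' per as-purchased kg (or litre).
#'
#' @param path Path to a CSV file with header
#'   `item_code,name,nova_group,subgroup,is_beef,energy_density_kcal_per_100g_edible,edible_fraction,carbon_intensity_gco2eq_per_kg,water_intensity_l_per_kg`.
#' @return A validated tibble with one row per food item.
#' @seealso [validate_food_reference()], [read_purchases()], [read_strata()]
#' @export
read_food_reference <- function(path) {
  df <- .read_table(
    path, .ref_csv_cols,
    readr::cols(
      item_code = readr::col_character(),
      name = readr::col_character(),
      nova_group = readr::col_integer(),
      subgroup = readr::col_character(),
      is_beef = readr::col_logical(),
      .default = readr::col_double()
    ),
    "food reference"
  )
  validate_food_reference(df)
}

#' Read a 7-day purchase diary from CSV
#'
#' Each record is the as-purchased quantity (kg or litres, summed over the
#' seven diary days) of one food item by one household. Item codes must
#' resolve against the food reference: a missing footprint coefficient would
#' silently bias totals, so unknown codes are a hard error unless
#' `allow_missing = TRUE`, in which case offending records are dropped and the
#' count reported.
#'
#' @param path Path to a CSV file with header
#'   `household_id,stratum_id,item_code,quantity_kg_7day`.
#' @param items Food reference table (see [read_food_reference()]).
#' @param allow_missing Drop records whose item code is absent from the
#'   reference instead of failing (default `FALSE`).
#' @return A tibble with one row per purchase record.
#' @export
read_purchases <- function(path, items, allow_missing = FALSE) {
  df <- .read_table(
    path, .purchases_csv_cols,
    readr::cols(
      household_id = readr::col_character(),
      stratum_id = readr::col_character(),
      item_code = readr::col_character(),
      quantity_kg_7day = readr::col_double()
    ),
    "purchases"
  )
  validate_purchases(df, items, allow_missing = allow_missing)
}

#' Validate a purchase table against a food reference
#'
#' @inheritParams read_purchases
#' @param purchases A data frame with columns `household_id`, `stratum_id`,
#'   `item_code`, `quantity`.
#' @return The validated tibble (with unknown-code records dropped when
#'   `allow_missing = TRUE`).
#' @export
validate_purchases <- function(purchases, items, allow_missing = FALSE) {
  purchases <- as_tibble(purchases)
  errors <- character()
  bad_q <- which(is.na(purchases$quantity) | purchases$quantity < 0)
  for (i in bad_q) {
    errors <- c(errors, sprintf(
      "row %d (item '%s'): quantity must be >= 0, got %s",
      i, purchases$item_code[i], purchases$quantity[i]
    ))
  }
  unknown <- !(purchases$item_code %in% items$item_code)
  if (any(unknown)) {
    if (allow_missing) {
      message(sprintf(
        "dropped %d purchase record(s) with item codes absent from the reference (%s)",
        sum(unknown),
        paste(head(unique(purchases$item_code[unknown]), 5L), collapse = ", ")
      ))
      purchases <- purchases[!unknown, ]
    } else {
      for (i in which(unknown)) {
        errors <- c(errors, sprintf(
          "row %d: unknown item_code '%s' (not in the food reference)",
          i, purchases$item_code[i]
        ))
      }
    }
  }
  .collect_errors(errors, "purchases")
  purchases
}

#' Read a stratum attribute table from CSV
#'
#' One row per sampling stratum (the unit of analysis): household and resident
#' counts, the expansion weight scaling the stratum to the population it
#' represents, and the adjustment covariates used by the regression models
#' (per-capita income, urban/rural area, macro-region, and the percentage of
#' household expenditure spent on out-of-home food).
#'
#' @param path Path to a CSV file with header
#'   `stratum_id,n_households,n_residents,expansion_weight,income,area,region,out_of_home_share_pct`.
#' @return A validated tibble with one row per stratum.
#' @export
read_strata <- function(path) {
  df <- .read_table(
    path, .strata_csv_cols,
    readr::cols(
      stratum_id = readr::col_character(),
      n_households = readr::col_integer(),
      n_residents = readr::col_integer(),
      area = readr::col_character(),
      region = readr::col_character(),
      .default = readr::col_double()
    ),
    "strata"
  )
  validate_strata(df)
}

#' Validate a stratum attribute table
#'
#' @param strata A data frame with columns `stratum_id`, `n_households`,
#'   `n_residents`, `expansion_weight`, `income`, `area`, `region`,
#'   `out_of_home_share`.
#' @return The validated tibble.
#' @export
validate_strata <- function(strata) {
  strata <- as_tibble(strata)
  errors <- character()
  say <- function(idx, msg) {
    sprintf("row %d (stratum '%s'): %s", idx, as.character(strata$stratum_id[idx]), msg)
  }
  dup <- duplicated(strata$stratum_id)
  for (i in which(dup)) errors <- c(errors, say(i, "duplicate stratum_id"))
  for (i in seq_len(nrow(strata))) {
    r <- strata[i, ]
    if (is.na(r$n_households) || r$n_households < 1) {
      errors <- c(errors, say(i, sprintf("n_households must be a positive integer, got %s", r$n_households)))
    }
    if (is.na(r$n_residents) || r$n_residents < 1) {
      errors <- c(errors, say(i, sprintf("n_residents must be a positive integer, got %s", r$n_residents)))
    } else if (!is.na(r$n_households) && r$n_residents < r$n_households) {
      errors <- c(errors, say(i, sprintf(
        "n_residents (%s) must be >= n_households (%s)", r$n_residents, r$n_households
      )))
    }
    if (is.na(r$expansion_weight) || r$expansion_weight <= 0) {
      errors <- c(errors, say(i, sprintf("expansion_weight must be > 0, got %s", r$expansion_weight)))
    }
    if (is.na(r$income) || !is.finite(r$income)) {
      errors <- c(errors, say(i, "income must be a finite number"))
    }
    if (is.na(r$area) || !(r$area %in% .df_areas)) {
      errors <- c(errors, say(i, sprintf(
        "area must be one of: %s; got '%s'", paste(.df_areas, collapse = ", "), r$area
      )))
    }
    if (is.na(r$region) || !(r$region %in% .df_regions)) {
      errors <- c(errors, say(i, sprintf(
        "region must be one of: %s; got '%s'", paste(.df_regions, collapse = ", "), r$region
      )))
    }
    if (is.na(r$out_of_home_share) || r$out_of_home_share < 0 || r$out_of_home_share > 100) {
      errors <- c(errors, say(i, sprintf(
        "out_of_home_share must be in [0, 100], got %s", r$out_of_home_share
      )))
    }
  }
  .collect_errors(errors, "strata")
  strata
}

.write_table <- function(df, path, col_map) {
  out <- df[, names(col_map)]
  names(out) <- unname(col_map)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write the three input tables back to their CSV formats
#'
#' Inverse of the corresponding readers: reading a written file yields the
#' original table. Used by the synthetic-data generator and handy for
#' exporting cleaned inputs.
#'
#' @param items,purchases,strata Tables as returned by the readers.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_food_reference <- function(items, path) .write_table(items, path, .ref_csv_cols)

#' @rdname write_food_reference
#' @export
write_purchases <- function(purchases, path) .write_table(purchases, path, .purchases_csv_cols)

#' @rdname write_food_reference
#' @export
write_strata <- function(strata, path) .write_table(strata, path, .strata_csv_cols)

#' Convert between edible fraction and correction factor
#'
#' Food-composition tables express the inedible-part adjustment either as an
#' edible fraction in (0, 1] (the share of purchased mass that is edible, the
#' convention used throughout this package) or as a multiplicative correction
#' factor >= 1 applied to the edible mass to recover the purchased mass. The
#' two are reciprocals.
#'
#' @param edible_fraction Numeric vector in (0, 1].
#' @param correction_factor Numeric vector >= 1.
#' @return The converted numeric vector.
#' @export
edible_fraction_to_correction <- function(edible_fraction) {
  if (any(is.na(edible_fraction) | edible_fraction <= 0 | edible_fraction > 1)) {
    stop("edible_fraction must be in (0, 1]", call. = FALSE)
  }
  1 / edible_fraction
}

#' @rdname edible_fraction_to_correction
#' @export
correction_to_edible_fraction <- function(correction_factor) {
  if (any(is.na(correction_factor) | correction_factor < 1)) {
    stop("correction_factor must be >= 1", call. = FALSE)
  }
  1 / correction_factor
}
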