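# Orchestration: run the full pipeline from the three CSV inputs and emit the
# report tables (Nova contribution table, quintile means, scenarios).
# Percentages, ratios and footprint means are rounded to 1 decimal at this
# reporting layer only; all internal computation is full precision.

.round1 <- function(x) round(x, 1)

#' Configuration of a pipeline run
#'
#' @param reference,purchases,strata Paths to the three input CSVs.
#' @param outdir Output directory for the report tables.
#' @param weighted Use expansion weights when building exposure quintiles
#'   (default `TRUE`).
#' @param with_interaction Include exposure product terms in the scenario
#'   prediction model (default `FALSE`).
#' @param allow_missing Drop purchase records with unknown item codes instead
#'   of failing (default `FALSE`).
#' @param verbose Emit progress messages (default `TRUE`).
#' @return A list of class `footprint_run_config`.
#' @export
run_config <- function(reference, purchases, strata, outdir = ".",
                       weighted = TRUE, with_interaction = FALSE,
                       allow_missing = FALSE, verbose = TRUE) {
  structure(
    list(
      reference = reference, purchases = purchases, strata = strata,
      outdir = outdir, weighted = isTRUE(weighted),
      with_interaction = isTRUE(with_interaction),
      allow_missing = isTRUE(allow_missing), verbose = isTRUE(verbose)
    ),
    class = "footprint_run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A `footprint_run_config` object.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

.say <- function(cfg, fmt, ...) {
  if (cfg$verbose) message(sprintf(fmt, ...))
  invisible(NULL)
}

.load_inputs <- function(cfg) {
  items <- read_food_reference(cfg$reference)
  purchases <- read_purchases(cfg$purchases, items, allow_missing = cfg$allow_missing)
  strata <- read_strata(cfg$strata)
  .say(
    cfg, "loaded %d food items, %d purchase records, %d strata",
    nrow(items), nrow(purchases), nrow(strata)
  )
  list(items = items, purchases = purchases, strata = strata)
}

.ensure_outdir <- function(cfg) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  invisible(cfg$outdir)
}

#' Run the footprint accounting stage
#'
#' Reads the inputs, summarises every stratum and builds the Nova contribution
#' table; writes `stratum_summaries.csv` (full precision) and
#' `contributions.csv` (percentages and ratios rounded to 1 decimal).
#'
#' @param cfg A `footprint_run_config` (see [run_config()]).
#' @return Invisibly, a list with the `summaries` and `contributions` tibbles.
#' @export
run_accounting <- function(cfg) {
  inputs <- .load_inputs(cfg)
  .ensure_outdir(cfg)
  summaries <- summarise_strata(inputs$purchases, inputs$items, inputs$strata)
  n_zero <- sum(is.na(summaries$carbon_per_1000kcal))
  .say(cfg, "summarised %d strata (%d excluded for zero energy)", nrow(summaries), n_zero)
  contributions <- contribution_table(inputs$purchases, inputs$items, inputs$strata)
  readr::write_csv(summaries, file.path(cfg$outdir, "stratum_summaries.csv"), progress = FALSE)
  contributions %>%
    mutate(across(c("pct_energy", "pct_carbon", "pct_water", "ratio_carbon", "ratio_water"), .round1)) %>%
    readr::write_csv(file.path(cfg$outdir, "contributions.csv"), progress = FALSE)
  invisible(list(summaries = summaries, contributions = contributions))
}

#' Run the quintile association stage
#'
#' Builds (expansion-weighted, unless configured otherwise) quintiles of the
#' beef and ultra-processed-food energy shares and fits the crude and adjusted
#' weighted models for both footprint outcomes: 2 exposures x 2 outcomes x 2
#' adjustments = 8 model blocks. Writes `quintile_means.csv` with the
#' population-averaged quintile means, robust standard errors, the weighted
#' mean exposure share per quintile, and the trend p-value.
#'
#' @inheritParams run_accounting
#' @return Invisibly, a list with `quintile_means` and the named list of
#'   `fits`.
#' @export
run_associations <- function(cfg) {
  inputs <- .load_inputs(cfg)
  .ensure_outdir(cfg)
  summaries <- summarise_strata(inputs$purchases, inputs$items, inputs$strata)
  strata <- inputs$strata
  fits <- list()
  rows <- list()
  for (exposure in c("beef", "upf")) {
    assignment <- assign_exposure_quintiles(summaries, strata, exposure, weighted = cfg$weighted)
    expo_means <- assignment %>%
      inner_join(strata %>% select("stratum_id", "expansion_weight"), by = "stratum_id") %>%
      group_by(.data$quintile) %>%
      summarise(
        exposure_mean = weighted.mean(.data$exposure_value, .data$expansion_weight),
        .groups = "drop"
      )
    for (outcome in .df_outcomes) {
      for (adjustment in c("crude", "adjusted")) {
        fit <- fit_quintile_model(summaries, assignment, strata, outcome, adjustment)
        fits[[paste(exposure, outcome, adjustment, sep = ".")]] <- fit
        rows[[length(rows) + 1L]] <- fit$adjusted_means %>%
          inner_join(expo_means, by = "quintile") %>%
          mutate(
            exposure = exposure, outcome = outcome, adjustment = adjustment,
            p_trend = fit$p_trend, .before = 1
          )
      }
    }
  }
  quintile_means <- bind_rows(rows) %>%
    select(
      "exposure", "outcome", "adjustment", "quintile",
      "exposure_mean", "mean", "se", "p_trend"
    )
  quintile_means %>%
    mutate(across(c("exposure_mean", "mean", "se"), .round1)) %>%
    readr::write_csv(file.path(cfg$outdir, "quintile_means.csv"), progress = FALSE)
  .say(cfg, "fitted %d quintile model blocks", length(fits))
  invisible(list(quintile_means = quintile_means, fits = fits))
}

#' Run the counterfactual scenario stage
#'
#' Predicts the population mean carbon and water footprint per 1000 kcal under
#' the baseline and the three first-quintile substitution scenarios, using the
#' joint covariate-adjusted model (main effects unless `with_interaction`).
#' Writes `scenarios.csv` with signed percent changes versus baseline.
#'
#' @inheritParams run_accounting
#' @return Invisibly, the scenarios tibble.
#' @export
run_scenarios <- function(cfg) {
  inputs <- .load_inputs(cfg)
  .ensure_outdir(cfg)
  summaries <- summarise_strata(inputs$purchases, inputs$items, inputs$strata)
  strata <- inputs$strata
  beef_a <- assign_exposure_quintiles(summaries, strata, "beef", weighted = cfg$weighted)
  upf_a <- assign_exposure_quintiles(summaries, strata, "upf", weighted = cfg$weighted)
  scen <- bind_rows(lapply(.df_outcomes, function(outcome) {
    predict_scenarios(summaries, beef_a, upf_a, strata,
      outcome = outcome, with_interaction = cfg$with_interaction
    )
  }))
  scen %>%
    mutate(
      predicted_mean = .round1(.data$predicted_mean),
      pct_change_vs_baseline = .round1(.data$pct_change)
    ) %>%
    select("scenario", "outcome", "predicted_mean", "pct_change_vs_baseline") %>%
    readr::write_csv(file.path(cfg$outdir, "scenarios.csv"), progress = FALSE)
  .say(cfg, "predicted %d scenario rows", nrow(scen))
  invisible(scen)
}

#' Run every pipeline stage
#'
#' @inheritParams run_accounting
#' @return Invisibly, a named list with the results of the three stages.
#' @export
run_all <- function(cfg) {
  invisible(list(
    accounting = run_accounting(cfg),
    associations = run_associations(cfg),
    scenarios = run_scenarios(cfg)
  ))
}

#' Bar chart of scenario footprint intensities
#'
#' @param scenarios A scenarios tibble as returned by [predict_scenarios()] or
#'   [run_scenarios()] (columns `scenario`, `outcome`, `predicted_mean`).
#' @return A ggplot object.
#' @export
plot_scenarios <- function(scenarios) {
  ggplot2::ggplot(
    scenarios,
    ggplot2::aes(
      x = .data$scenario, y = .data$predicted_mean, fill = .data$outcome
    )
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = NULL, y = "footprint per 1000 kcal",
      title = "Predicted footprint intensity by scenario"
    ) +
    ggplot2::theme_minimal()
}
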