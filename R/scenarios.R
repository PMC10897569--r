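# Counterfactual "first-quintile" scenarios by marginal standardisation
# (G-computation): fit the joint adjusted main-effects model in both exposure
# quintile sets, then predict every stratum with one or both quintile
# indicators forced to 1 while leaving the covariates untouched, and
# weighted-average the predictions.

#' Percent change of a scenario value relative to baseline
#'
#' `(scenario_value - baseline_value) / baseline_value * 100`; negative values
#' are reductions. Full precision is returned; report rounded to 1 decimal.
#'
#' @param baseline_value Baseline footprint intensity (must be > 0).
#' @param scenario_value Scenario footprint intensity, same units; vectorised.
#' @return Signed percent change.
#' @export
percent_change <- function(baseline_value, scenario_value) {
  if (any(!is.finite(baseline_value)) || any(baseline_value <= 0)) {
    stop("baseline_value must be > 0", call. = FALSE)
  }
  (scenario_value - baseline_value) / baseline_value * 100
}

#' Predict counterfactual footprint intensities under reduced-consumption scenarios
#'
#' Using the joint covariate-adjusted weighted linear model with both exposure
#' quintile indicator sets (main effects only by default, justified when the
#' interaction Wald test is non-significant; set `with_interaction = TRUE` to
#' include the product terms), predicts the population mean footprint
#' intensity per 1000 kcal under:
#'
#' * `baseline` -- observed data (the weighted mean fitted value, which equals
#'   the weighted mean observed outcome for a weighted fit with intercept);
#' * `S1_upf_q1` -- every stratum moved to the first ultra-processed-food
#'   quintile;
#' * `S2_beef_q1` -- every stratum moved to the first beef quintile;
#' * `S3_both_q1` -- both exposures moved to their first quintiles.
#'
#' Covariates keep their observed values throughout, so each scenario mean is
#' a population-averaged (expansion-weight-weighted) predictive margin.
#'
#' @inheritParams interaction_wald
#' @param with_interaction Include beef-by-UPF quintile product terms in the
#'   prediction model (default `FALSE`).
#' @return A tibble with one row per scenario: `scenario`, `outcome`,
#'   `predicted_mean` and `pct_change` versus baseline (0 for the baseline
#'   row).
#' @export
predict_scenarios <- function(summaries, beef_assignment, upf_assignment, profiles,
                              outcome = c("carbon_per_1000kcal", "water_per_1000kcal"),
                              adjustment = c("adjusted", "crude"),
                              with_interaction = FALSE) {
  outcome <- match.arg(outcome)
  adjustment <- match.arg(adjustment)
  d <- .model_frame(
    summaries,
    list(beef_q = beef_assignment, upf_q = upf_assignment),
    profiles, outcome
  )
  main <- if (with_interaction) "beef_q * upf_q" else c("beef_q", "upf_q")
  rhs <- c(main, if (adjustment == "adjusted") .df_covariates)
  fit <- .wls(reformulate(rhs, response = outcome), d)
  w <- d$expansion_weight
  margin <- function(beef_to_q1 = FALSE, upf_to_q1 = FALSE) {
    dq <- d
    if (beef_to_q1) dq$beef_q <- factor(1, levels = 1:5)
    if (upf_to_q1) dq$upf_q <- factor(1, levels = 1:5)
    weighted.mean(predict(fit, newdata = dq), w)
  }
  baseline <- weighted.mean(fitted(fit), w)
  s1 <- margin(upf_to_q1 = TRUE)
  s2 <- margin(beef_to_q1 = TRUE)
  s3 <- margin(beef_to_q1 = TRUE, upf_to_q1 = TRUE)
  tibble(
    scenario = c("baseline", "S1_upf_q1", "S2_beef_q1", "S3_both_q1"),
    outcome = outcome,
    predicted_mean = c(baseline, s1, s2, s3),
    pct_change = c(0, percent_change(baseline, c(s1, s2, s3)))
  )
}
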