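# Weighted least-squares association models of footprint intensity against
# exposure quintiles. Expansion weights enter as analytic weights; standard
# errors are heteroskedasticity-robust (HC3 sandwich), the closest analogue of
# the usual survey-software default short of a full design-based linearised
# variance, which is out of scope.

.df_outcomes <- c("carbon_per_1000kcal", "water_per_1000kcal")
.df_covariates <- c("income", "area", "region", "out_of_home_share")

# Join summaries, quintile assignments and profiles into a model frame.
# `assignments` is a named list, e.g. list(beef_q = tbl, upf_q = tbl).
.model_frame <- function(summaries, assignments, profiles, outcome) {
  d <- summaries %>% inner_join(profiles, by = "stratum_id")
  for (nm in names(assignments)) {
    a <- assignments[[nm]] %>%
      select("stratum_id", quintile = "quintile")
    names(a)[2] <- nm
    d <- d %>% inner_join(a, by = "stratum_id")
    d[[nm]] <- factor(d[[nm]], levels = 1:5)
  }
  d$area <- factor(d$area, levels = .df_areas)
  d$region <- factor(d$region, levels = .df_regions)
  drop <- is.na(d[[outcome]])
  if (any(drop)) {
    message(sprintf("excluding %d stratum(s) with undefined %s", sum(drop), outcome))
    d <- d[!drop, , drop = FALSE]
  }
  d
}

.check_full_rank <- function(fit) {
  b <- coef(fit)
  if (anyNA(b)) {
    stop(sprintf(
      "model is rank deficient; collinear term(s): %s",
      paste(names(b)[is.na(b)], collapse = ", ")
    ), call. = FALSE)
  }
  invisible(fit)
}

.robust_vcov <- function(fit) sandwich::vcovHC(fit, type = "HC3")

.wls <- function(formula, data) {
  # weights is evaluated inside `data`, so refer to the column by name
  fit <- lm(formula, data = data, weights = expansion_weight)
  .check_full_rank(fit)
  fit
}

# Population-averaged predictive margin for quintile level q: set every
# stratum's quintile to q, keep observed covariates, weighted-average the
# linear predictions. Standard error by the delta method on the robust vcov.
.margins <- function(fit, data, qvar, V, weights) {
  tt <- delete.response(terms(fit))
  b <- coef(fit)
  res <- lapply(1:5, function(q) {
    dq <- data
    dq[[qvar]] <- factor(q, levels = 1:5)
    X <- model.matrix(tt, dq, xlev = fit$xlevels)
    cbar <- colSums(weights * X) / sum(weights)
    tibble(
      quintile = q,
      mean = drop(cbar %*% b),
      se = sqrt(drop(t(cbar) %*% V %*% cbar))
    )
  })
  bind_rows(res)
}

# Integer-scored trend refit shared by trend_test() and fit_quintile_model().
.trend_fit <- function(data, outcome, qvar, adjustment) {
  data$quintile_score <- as.numeric(as.character(data[[qvar]]))
  rhs <- c("quintile_score", if (adjustment == "adjusted") .df_covariates)
  fit <- .wls(reformulate(rhs, response = outcome), data)
  V <- .robust_vcov(fit)
  est <- coef(fit)[["quintile_score"]]
  se <- sqrt(V["quintile_score", "quintile_score"])
  p <- if (se > 0) 2 * pt(-abs(est / se), df.residual(fit)) else NA_real_
  list(estimate = est, se = se, p = p, df = df.residual(fit))
}

#' Fit a weighted quintile model of footprint intensity
#'
#' Weighted least squares of a per-1000-kcal footprint intensity on indicator
#' variables for exposure quintiles 2--5 (quintile 1 is the reference). The
#' adjusted model adds per-capita income (continuous), area (urban reference),
#' macro-region (Southeast reference) and the out-of-home expenditure share
#' (continuous). Expansion weights are used as analytic weights and inference
#' is based on an HC3 sandwich covariance (the small-sample-robust variant).
#'
#' Quintile means are population-averaged predictive margins: every stratum is
#' set to quintile q with its observed covariates, and the predictions are
#' averaged with the expansion weights. The trend p-value comes from refitting
#' the model with the integer quintile score 1--5 in place of the indicators.
#'
#' @param summaries Stratum diet summaries (see [summarise_strata()]).
#' @param assignment Quintile assignment for one exposure
#'   (see [assign_exposure_quintiles()]).
#' @param profiles Stratum attribute table.
#' @param outcome `"carbon_per_1000kcal"` or `"water_per_1000kcal"`.
#' @param adjustment `"crude"` or `"adjusted"`.
#' @return An object of class `quintile_fit`: a list with the underlying `lm`
#'   fit, robust `vcov`, `adjusted_means` (tibble of quintile, mean, se),
#'   `p_trend`, `trend` (estimate and se of the score coefficient), `outcome`,
#'   `adjustment`, `exposure` and `n_strata`.
#' @export
fit_quintile_model <- function(summaries, assignment, profiles,
                               outcome = c("carbon_per_1000kcal", "water_per_1000kcal"),
                               adjustment = c("crude", "adjusted")) {
  outcome <- match.arg(outcome)
  adjustment <- match.arg(adjustment)
  d <- .model_frame(summaries, list(quintile = assignment), profiles, outcome)
  rhs <- c("quintile", if (adjustment == "adjusted") .df_covariates)
  fit <- .wls(reformulate(rhs, response = outcome), d)
  V <- .robust_vcov(fit)
  tr <- .trend_fit(d, outcome, "quintile", adjustment)
  structure(
    list(
      fit = fit,
      vcov = V,
      adjusted_means = .margins(fit, d, "quintile", V, d$expansion_weight),
      p_trend = tr$p,
      trend = tr[c("estimate", "se")],
      outcome = outcome,
      adjustment = adjustment,
      exposure = assignment$exposure[1],
      n_strata = nrow(d)
    ),
    class = "quintile_fit"
  )
}

#' @export
print.quintile_fit <- function(x, ...) {
  cat(sprintf(
    "Weighted quintile model (%s): %s vs %s exposure, %d strata\n",
    x$adjustment, x$outcome, x$exposure, x$n_strata
  ))
  m <- x$adjusted_means
  cat(sprintf(
    "  Q%d mean %.1f (se %.1f)\n", m$quintile, m$mean, m$se
  ), sep = "")
  cat(sprintf("  P for trend: %.3g\n", x$p_trend))
  invisible(x)
}

#' Linear trend test across exposure quintiles
#'
#' Refits the quintile model with the integer score 1--5 replacing the
#' indicator variables and returns the two-sided p-value of the score
#' coefficient under the HC3 robust variance ("P for trend").
#'
#' @inheritParams fit_quintile_model
#' @return The p-value, with attributes `estimate` (per-quintile slope), `se`
#'   and `df`.
#' @export
trend_test <- function(summaries, assignment, profiles,
                       outcome = c("carbon_per_1000kcal", "water_per_1000kcal"),
                       adjustment = c("crude", "adjusted")) {
  outcome <- match.arg(outcome)
  adjustment <- match.arg(adjustment)
  d <- .model_frame(summaries, list(quintile = assignment), profiles, outcome)
  tr <- .trend_fit(d, outcome, "quintile", adjustment)
  structure(tr$p, estimate = tr$estimate, se = tr$se, df = tr$df)
}

#' Dose-response slope of footprint intensity per percentage point of exposure
#'
#' Weighted least squares of a per-1000-kcal intensity on the two continuous
#' exposure shares jointly (beef and ultra-processed % of energy), optionally
#' with the covariate adjustment set. Useful for validation against generators
#' with a known linear effect: the coefficient of one exposure is the change
#' in intensity per percentage point of that exposure holding the other fixed.
#'
#' @inheritParams fit_quintile_model
#' @param exposure Which exposure's coefficient to report: `"beef"` or
#'   `"upf"`.
#' @param conf_level Confidence level for the robust interval (default 0.95).
#' @return A one-row tibble: `exposure`, `outcome`, `adjustment`, `estimate`,
#'   `se`, `conf_low`, `conf_high`, `p_value`, `n_strata`.
#' @export
fit_exposure_slope <- function(summaries, profiles,
                               exposure = c("beef", "upf"),
                               outcome = c("carbon_per_1000kcal", "water_per_1000kcal"),
                               adjustment = c("crude", "adjusted"),
                               conf_level = 0.95) {
  exposure <- match.arg(exposure)
  outcome <- match.arg(outcome)
  adjustment <- match.arg(adjustment)
  d <- .model_frame(summaries, list(), profiles, outcome)
  rhs <- c("pct_energy_beef", "pct_energy_upf",
           if (adjustment == "adjusted") .df_covariates)
  fit <- .wls(reformulate(rhs, response = outcome), d)
  V <- .robust_vcov(fit)
  term <- paste0("pct_energy_", exposure)
  est <- coef(fit)[[term]]
  se <- sqrt(V[term, term])
  tq <- qt(1 - (1 - conf_level) / 2, df.residual(fit))
  tibble(
    exposure = exposure,
    outcome = outcome,
    adjustment = adjustment,
    estimate = est,
    se = se,
    conf_low = est - tq * se,
    conf_high = est + tq * se,
    p_value = if (se > 0) 2 * pt(-abs(est / se), df.residual(fit)) else NA_real_,
    n_strata = nrow(d)
  )
}

#' Wald test for beef-by-ultra-processed quintile interaction
#'
#' Fits the joint adjusted model with both quintile indicator sets plus their
#' 16 product terms and tests, with the HC3 robust covariance, the null that
#' all product coefficients are zero (chi-squared Wald test).
#'
#' @inheritParams fit_quintile_model
#' @param beef_assignment,upf_assignment Quintile assignments for the beef and
#'   ultra-processed-food exposures.
#' @return The p-value, with attributes `statistic` (chi-squared) and `df`.
#' @export
interaction_wald <- function(summaries, beef_assignment, upf_assignment, profiles,
                             outcome = c("carbon_per_1000kcal", "water_per_1000kcal"),
                             adjustment = c("crude", "adjusted")) {
  outcome <- match.arg(outcome)
  adjustment <- if (missing(adjustment)) "adjusted" else match.arg(adjustment)
  d <- .model_frame(
    summaries,
    list(beef_q = beef_assignment, upf_q = upf_assignment),
    profiles, outcome
  )
  rhs <- c("beef_q * upf_q", if (adjustment == "adjusted") .df_covariates)
  fit <- lm(reformulate(rhs, response = outcome), data = d, weights = expansion_weight)
  b_all <- coef(fit)
  int_all <- grep("^beef_q[0-9]+:upf_q[0-9]+$", names(b_all), value = TRUE)
  main <- setdiff(names(b_all), int_all)
  if (anyNA(b_all[main])) {
    stop(sprintf(
      "model is rank deficient; collinear term(s): %s",
      paste(main[is.na(b_all[main])], collapse = ", ")
    ), call. = FALSE)
  }
  # an empty beef-by-UPF cell leaves its product term inestimable; test the
  # estimable ones with correspondingly reduced degrees of freedom
  aliased <- int_all[is.na(b_all[int_all])]
  if (length(aliased) > 0) {
    message(sprintf(
      "%d empty exposure cell(s); dropping product term(s): %s",
      length(aliased), paste(aliased, collapse = ", ")
    ))
  }
  int_terms <- setdiff(int_all, aliased)
  V <- .robust_vcov(fit)
  if (any(!is.finite(V[int_terms, int_terms]))) {
    # single-stratum cells have leverage one, where the HC3 weights are
    # undefined; fall back to the HC1 sandwich for this test
    message("single-stratum exposure cell(s) make HC3 weights degenerate; using HC1 for the interaction Wald test")
    V <- sandwich::vcovHC(fit, type = "HC1")
  }
  b <- b_all[int_terms]
  W <- drop(t(b) %*% solve(V[int_terms, int_terms]) %*% b)
  df <- length(int_terms)
  structure(pchisq(W, df = df, lower.tail = FALSE), statistic = W, df = df)
}
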