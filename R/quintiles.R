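# Survey-weighted quintile construction for the two dietary exposures.

#' Assign weighted quantile groups
#'
#' Splits values into `n_groups` groups of (approximately) equal total weight:
#' cut-points sit at weighted cumulative probabilities 1/n, 2/n, ... over the
#' values sorted ascending. Tied values all take the group of their first
#' (lowest-rank) occurrence, so the assignment is a function of the value.
#' Assignments are invariant to rescaling all weights by a positive constant.
#'
#' @param values Numeric exposure values (one per stratum).
#' @param weights Positive weights (expansion weights); `NULL` for equal
#'   weights.
#' @param n_groups Number of groups (default 5, i.e. quintiles).
#' @return Integer vector of group indices (1 = lowest exposure), aligned with
#'   `values`.
#' @export
assign_weighted_quintiles <- function(values, weights = NULL, n_groups = 5L) {
  m <- length(values)
  if (is.null(weights)) weights <- rep(1, m)
  if (length(weights) != m) {
    stop("values and weights must have the same length", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(!is.finite(weights))) {
    stop("values and weights must be finite and non-missing", call. = FALSE)
  }
  if (any(weights <= 0)) stop("weights must be > 0", call. = FALSE)
  if (m < n_groups) {
    stop(sprintf("need at least %d observations for %d groups", n_groups, n_groups),
      call. = FALSE
    )
  }
  if (length(unique(values)) < n_groups) {
    stop(sprintf(
      "fewer than %d distinct exposure values; use fewer groups", n_groups
    ), call. = FALSE)
  }
  ord <- order(values)
  cw <- cumsum(weights[ord]) / sum(weights)
  q <- as.integer(pmax(1L, ceiling(pmin(cw, 1) * n_groups - 1e-9)))
  vs <- values[ord]
  uv <- vs[!duplicated(vs)]
  q <- q[!duplicated(vs)][match(vs, uv)]
  out <- integer(m)
  out[ord] <- q
  out
}

#' Build quintile assignments of an exposure across strata
#'
#' Convenience wrapper pairing [assign_weighted_quintiles()] with the diet
#' summaries: extracts the exposure share (`pct_energy_beef` or
#' `pct_energy_upf`), drops strata where it is undefined (zero energy), and
#' weights by expansion weight unless `weighted = FALSE`.
#'
#' @param summaries Stratum diet summaries (see [summarise_strata()]).
#' @param profiles Stratum attribute table.
#' @param exposure `"beef"` or `"upf"`.
#' @param weighted Use expansion weights for the quintile cut-points
#'   (default `TRUE`); `FALSE` gives unweighted quintiles for sensitivity
#'   analyses.
#' @param n_groups Number of exposure groups (default 5).
#' @return A tibble with columns `stratum_id`, `exposure`, `exposure_value`
#'   (% energy) and `quintile` (integer 1--`n_groups`).
#' @export
assign_exposure_quintiles <- function(summaries, profiles,
                                      exposure = c("beef", "upf"),
                                      weighted = TRUE, n_groups = 5L) {
  exposure <- match.arg(exposure)
  col <- paste0("pct_energy_", exposure)
  d <- summaries %>%
    inner_join(profiles %>% select("stratum_id", "expansion_weight"),
      by = "stratum_id"
    ) %>%
    filter(!is.na(.data[[col]]))
  w <- if (weighted) d$expansion_weight else NULL
  tibble(
    stratum_id = d$stratum_id,
    exposure = exposure,
    exposure_value = d[[col]],
    quintile = assign_weighted_quintiles(d[[col]], w, n_groups = n_groups)
  )
}
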