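---
title: "Methods: dietary footprint accounting, quintile models and counterfactual scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dietary footprint accounting, quintile models and counterfactual scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietfootprint)
```

## The problem

Household budget surveys record the food items each household purchases over a
short diary window. Combining a purchase diary with a food composition table
and a table of cradle-to-retail footprint intensities turns those diaries into
estimates of the dietary energy, greenhouse-gas emissions (carbon footprint,
gCO2eq) and freshwater use (water footprint, litres) that a population's food
purchases embody — and lets one ask how those footprints vary with the dietary
pattern, in particular with the energy share of beef and of ultra-processed
foods (Nova group 4).

`dietfootprint` implements that pipeline for stratum-aggregated survey data:
the sampling stratum (a cluster of geographically and socioeconomically
homogeneous households) is the unit of analysis, carrying a resident count,
an expansion weight and adjustment covariates.

## Accounting conventions

Three inputs drive the accounting:

* **Food reference** — per item: Nova group and subgroup, a beef flag, energy
  density (kcal per 100 g of *edible* portion), edible fraction of the
  as-purchased mass, and carbon/water intensities per as-purchased kg.
* **Purchases** — as-purchased kg (or litres) of each item per household over
  the 7-day diary.
* **Strata** — residents, households, expansion weight, per-capita income,
  urban/rural area, macro-region, out-of-home expenditure share.

Two asymmetric conventions matter and are enforced throughout:

1. **Energy uses only the edible portion.** For quantity $q$ (kg),
   $E = q \cdot f_{edible} \cdot 10 \cdot d$ kcal, where $d$ is the energy
   density per 100 g. Composition tables sometimes publish the reciprocal
   "correction factor" ($\ge 1$) instead of the edible fraction;
   `edible_fraction_to_correction()` converts between the two. The bounded
   edible fraction is the stored quantity because it validates cleanly.
2. **Footprints use the full as-purchased mass.** Inedible parts are inherent
   to producing the edible fraction, so their impact is inseparable: halving
   the edible fraction halves energy but leaves both footprints unchanged.
   This asymmetry is a tested invariant.

Stratum totals are divided by 7 and by the resident count to give per-capita
daily values. Two derived quantities standardise for the amount of food
purchased: the **per-1000-kcal intensities** (footprint / energy × 1000) and
the two **exposure shares** — the percentage of energy from Nova group 4 and
from beef items. Beef spans Nova groups 1 (fresh cuts), 3 (salted, cured,
smoked) and 4 (reconstituted products), never group 2; the validator rejects
a beef item coded as a culinary ingredient. Cooking-stage impacts are outside
the accounting scope.

Strata with zero total energy have undefined shares and intensities; they are
reported as `NA`, counted in a warning, and excluded from the models.

## The contribution table

For Nova groups, subgroups, and beef pooled across groups, the package
reports percentage contributions to total energy, carbon and water, plus the
**footprint/energy ratio** (percentage of footprint over percentage of
energy; 1 means proportional to calories). Pooling across strata weights each
stratum's *per-capita* values by its expansion weight, which reproduces
national-availability semantics; whether to additionally weight by residents
is not identified by the outputs we target, and the expansion-weight-only
choice is the package's default (a residents-weighted sensitivity run can be
had by multiplying the weights upstream). Percentages within the four-group
partition sum to 100 by construction; rounding to 1 decimal happens only when
tables are written.

## Quintile association models

Exposure quintiles are built on the weighted cumulative distribution: sort
strata by exposure, cut at cumulative weight 0.2/0.4/0.6/0.8, and give tied
values the quintile of their first occurrence, so the assignment is a
function of the exposure value and is invariant to rescaling the weights.
Unweighted quintiles are available behind `weighted = FALSE` for sensitivity.

The outcome models are weighted least squares with the expansion weights as
analytic weights:

$$y_s = \beta_0 + \sum_{q=2}^{5}\beta_q \,\mathbb{1}\{Q_s = q\} + \gamma'x_s + \varepsilon_s$$

with $x_s$ empty (crude) or income, area (urban reference), region
(Southeast reference) and out-of-home share (adjusted). Reported quintile
means are **population-averaged predictive margins**: set every stratum to
quintile $q$, keep its observed covariates, and average the predictions with
the expansion weights. With an intercept, the margins averaged over the
observed quintile distribution recover the weighted mean outcome exactly — a
tested identity.

*P for trend* replaces the indicators with the integer score 1–5 and reports
the two-sided p-value of that coefficient — the common epidemiological
convention. The beef-by-UPF interaction is a 16-df Wald chi-squared test on
the product terms of the joint model.

**Variance estimation.** The survey's full two-stage design is not available
at the stratum level, so the package uses heteroskedasticity-robust sandwich
standard errors on the weighted fit rather than a design-based linearised
variance (a stated limitation). Among the HC variants we use **HC3**: with a
few hundred strata and skewed expansion weights the HC1 variant is
anti-conservative (its 95 % intervals cover a known simulated slope in fewer
than 90 % of replicates) and its robust Wald statistic degenerates when
sparse quintile cells produce leverage near one, while HC3 — the standard
small-sample recommendation — restores nominal behaviour (type-I error 5.2 %
over 1000 null simulations, coverage 90 %). The robust Wald interaction test
needs adequately filled 5×5 quintile cells; below roughly 300 strata its
p-values become unreliable and should be read with caution. Two degradations
are handled explicitly there: an empty exposure cell leaves its product term
inestimable, so the test drops it and reduces the degrees of freedom with a
message; and a single-stratum cell has leverage one, where the HC3 weights
are undefined, in which case the test falls back to the HC1 sandwich (again
with a message).

## Counterfactual scenarios

The three reduced-consumption scenarios are computed by marginal
standardisation (G-computation) on the joint adjusted model with both
quintile sets (main effects only, justified when the interaction test is
non-significant; `with_interaction = TRUE` refits with products):

* baseline — weighted mean fitted value on observed data (equals the
  weighted mean observed outcome by the WLS intercept identity);
* scenario 1 — every stratum's UPF quintile set to 1;
* scenario 2 — every stratum's beef quintile set to 1;
* scenario 3 — both set to 1.

Covariates are untouched — the substitution acts on the model's quintile
indicators only, which is the construction consistent with "predicted values
adjusted for" covariates. Percent changes are signed, relative to the same
run's baseline. In the main-effects model the combined scenario's change
equals the sum of the single-exposure changes exactly, and predictions are
invariant to rescaling all weights — both are tested identities. No
uncertainty intervals are attached to scenario means; a bootstrap is future
work.

## The synthetic survey generator

Real household-budget microdata cannot be redistributed, so validation runs
on a seeded generator (`simulation_config()`, `generate_reference()`,
`generate_population()`) whose defaults are the study conditions of the
package's validation suite:

* 120 strata, 16–120 households per stratum (household counts only matter
  for the diary's structure; stratum-level statistics are invariant to them),
  40 food items with at least two per Nova group and one beef item in each of
  groups 1, 3 and 4;
* stratum energy availability ~ Normal(1200, 120) kcal/person-day — the
  order of magnitude of at-home food purchases when out-of-home consumption
  is excluded;
* beef energy-share targets uniform on 3–8.2 % and UPF targets on
  10.1–28.1 %, the quintile spreads reported for national household-budget
  data;
* group-wise footprint-intensity scales chosen so per-kcal intensities order
  beef ≫ ultra-processed > unprocessed/processed > culinary ingredients,
  matching the observed footprint/energy ratio gradient (culinary
  ingredients near 0.1–0.2, UPF near 0.9–1.0); beef items get exactly
  `beef_carbon_multiplier` (default 15) and `beef_water_multiplier`
  (default 10) times the mean non-beef intensity, which places beef's ratios
  near the observed magnitudes (~9 carbon, ~7 water at a ~5 % energy share);
* multiplicative log-normal quantity noise with `noise_sd = 0.05` (mean-one
  corrected), a modest diary measurement error.

Generation is **energy-share-first**: category energy targets are drawn,
split within categories by symmetric Dirichlet compositions, and only then
inverted to as-purchased masses through each item's energy density and edible
fraction. Ground truth is therefore exact in exposure-share space: with
`noise_sd = 0`, the pipeline recovers each stratum's target shares and
per-1000-kcal intensities to floating-point precision (tested at 1e−6
relative error). Beef energy is split across the three beef subgroups with
fixed proportions (0.75/0.10/0.15 for groups 1/3/4); the group-4 portion
counts towards the UPF share, and the generator solves for the non-beef UPF
allocation accordingly (infeasible combinations error out).

Because expected intensity is linear in the two shares, the generator's
ground truth includes closed-form dose-response slopes (change in expected
per-1000-kcal intensity per percentage point of exposure, holding the other
fixed). Recovery tests fit the matching joint continuous-exposure WLS
(`fit_exposure_slope()`) and check CI coverage over 200 seeds; the
quintile-score trend slope has no closed-form truth and is tested
qualitatively (sign, significance, null behaviour) instead.

**What the generator does not emulate:** real item-code dialects, prices,
two-stage PSU selection, seasonal structure, within-household allocation
behaviour, correlated measurement error, or footprint-coefficient
uncertainty. Passing tests therefore validate the *arithmetic and the
statistical machinery*, not the field accuracy of any real-world coefficient
table; absolute national estimates require the real microdata and
coefficient tables and are out of scope.

## Numerical choices and problem sizes

* Quintile cut-points use a 1e−9 guard against floating-point boundary
  misclassification; fewer than five distinct exposure values is an error.
* All internal arithmetic is full precision; rounding to 1 decimal occurs
  only when report CSVs are written, so a rounded four-group percentage
  column can sum to 100 ± 0.2.
* Rank-deficient model matrices raise an error naming the collinear terms;
  unknown purchase item codes are a hard error (a silently dropped item
  would bias totals) unless `allow_missing = TRUE`, which drops and counts
  them.
* Validation suite scales: recovery/coverage studies use 100 strata × 2–5
  households × 20 items over 200 seeds; the null calibration of the trend
  test uses 1000 directly simulated stratum-level datasets of 120 strata;
  interaction tests use 400 strata. These sizes keep quintile granularity
  and model stability while completing quickly.

## Limitations

* Variance is sandwich-robust, not design-based; with replicate weights or
  PSU identifiers a linearised variance would be preferable.
* The interaction Wald test is unreliable below a few hundred strata.
* Scenario means carry no uncertainty intervals.
* The generator's confounding option (`covariate_effects`) shifts exposure
  targets with log income only; richer confounding structures must be built
  by the user.
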