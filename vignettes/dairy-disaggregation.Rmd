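---
title: "Disaggregating dairy from composite foods: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disaggregating dairy from composite foods: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dairydisagg)
```

## The problem

National diet surveys record *foods* (a croissant, a lasagna, a latte), but
dairy policy and environmental accounting need *commodities* (grams of
milk, cheese, yogurt, cream, butter). Much of the dairy a population eats
arrives inside composite foods — cheese on pizza, milk in pancake batter —
and is invisible to an analysis that only counts foods filed under dairy
food groups. Conversely, foods filed under dairy groups (fruit yogurts,
ice-cream cones) are not 100% dairy. `dairydisagg` implements the
disaggregation pipeline that resolves each food through a hierarchical
recipe database into base-ingredient masses, classifies those ingredients
against a dairy taxonomy, and propagates the result through survey-weighted
intake estimation and a milk-equivalent greenhouse-gas conversion.

## Recipe resolution

A recipe database maps each food code to component masses per 100 g of
product; components may themselves be foods with recipes, forming a
directed acyclic graph. `resolve_recipe()` expands this recursively: a
sub-recipe contributing $g$ grams per 100 g of its parent contributes
$g/100$ of its own per-100 g composition, and base-ingredient masses met
along several paths are summed. Three conventions matter:

* **No renormalisation.** Per-100 g masses are used as recorded, because
  recipe amounts are pre-cooking ingredient weights and the environmental
  burden arises from the product as produced, not as consumed (water loss
  in cooking is deliberately not modelled). A configurable validity window
  (default 50–130 g per 100 g) flags suspect recipes with a warning; only
  a non-positive mass sum is an error.
* **Cycles are hard errors.** A recipe hierarchy is expected to be acyclic;
  a cycle indicates corrupt input and is reported with the codes involved,
  never silently truncated.
* **Deterministic output.** Resolved tables are sorted by ingredient code
  so downstream outputs are byte-reproducible.

The resolver is certified against an independent oracle,
`flatten_by_paths()`, which enumerates every root-to-leaf path and
multiplies fractions along it — exponential but obviously correct. The two
implementations share no code and are compared exactly on randomized
databases (up to 30 foods, nesting depth up to 4) in the test suite.

## The dairy taxonomy

Each base ingredient is either dairy — labelled with a (category,
fat level, cheese variety) triple — or explicitly non-dairy. Categories are
milk, cheese, yogurt, cream, butter; fat level (skimmed / semiskimmed /
full fat) applies to all categories except butter, with cream restricted to
semiskimmed or full fat; variety (cheddar / cottage / other) applies to
cheese only. An ingredient found in neither roster raises an error rather
than defaulting to non-dairy: the classification is produced by human
coders and is complete by construction, so a gap signals data drift and
should stop the pipeline, not bias it.

## Profiles and food classes

`dairy_profile()` sums resolved ingredient masses within each subtype
triple, giving grams of each dairy subtype per 100 g of food. Foods are
classed **structurally**: *pure dairy* means every resolved ingredient is
dairy-classified; *non-dairy* means zero dairy mass; everything else is
*composite dairy*. The structural definition, rather than a mass threshold,
is what makes salted butter — 98.44 g dairy per 100 g — a composite: the
1.56 g of salt is not dairy.

```{r}
fx <- dairy_fixtures()
dairy_profile(fx$db, fx$map, "croissant")
dairy_profile(fx$db, fx$map, "salted_butter")$food_class
```

Subtype keys are the full triple; reports aggregate upward (category, then
total), so fat-level tables and category tables come from one structure.
Percentages are carried at full precision and rounded only at reporting
time, to the nearest integer with halves away from zero
(`round_half_away()`).

## Intake estimation and the two modes

`person_daily_intake()` computes each respondent's daily dairy intake from
up to two 24-h recall days:

* **disaggregated** — each item contributes
  `grams_consumed × subtype_g_per_100g / 100`;
* **food_group** (the naive, "without disaggregation" mode) — an item whose
  food group is mapped to a dairy category contributes its full reported
  weight to that category; every other item contributes nothing. This is
  the only definition of "not disaggregating" consistent with the observed
  sign pattern of the bias: yogurt and cream are overestimated (fruit
  yogurts and ice creams count fully) while cheese and butter are
  underestimated (they mostly arrive inside composites).

Day totals are averaged over the person's completed days (1 or 2) before
weighting across persons — the day-combination rule is isolated in one
function so an alternative convention is a one-line change. Estimates are
per capita: non-consumers contribute zeros.

`population_mean()` uses the weighted mean $\sum w_i x_i / \sum w_i$ and a
weighted SD from the variance
$\frac{\sum w_i (x_i - \bar x_w)^2}{\sum w_i}\cdot\frac{n}{n-1}$.
This form is invariant to rescaling all weights by a constant — a property
calibration weights must have, and one the test suite asserts — and reduces
to the ordinary sample SD under equal weights. Design-based variance
(strata, clusters, finite-population corrections) is out of scope.

`bias_report()` expresses the mode difference as
$100(\bar x_{with} - \bar x_{without})/d$ with the denominator $d$ an
explicit parameter (`denominator_with` or `denominator_without`), because
published percent-difference figures are computed under both conventions
and the package refuses to guess; the convention is recorded on every
report. Positive values mean the naive mode underestimates.

`contribution_shares()` attributes weighted disaggregated dairy mass to the
food group each food is filed under, and rolls groups up into
*noncomposite* (groups mapped to a dairy category) versus *composite*
(everything else).

## Emissions

`to_milk_equivalents()` converts g/day by category into litres of raw milk
per day via litres-per-kg factors; `annual_per_capita_emissions()`
multiplies by 365 and by a milk carbon footprint (default 1.2 kg CO2e/L,
the UK figure). Conventions:

* Milk converts through a density the source material never states;
  default 1.03 kg/L, configurable.
* Factors are category-level by default with variety-level overrides; the
  only published utilisation figure wired in is cheddar at 9.5 L of milk
  per kg of cheese. The remaining defaults (yogurt 1.0, cream 8, butter
  20 L/kg) are package conventions chosen from typical dairy-processing
  yields and should be replaced with authoritative utilisation data via
  `load_milk_equivalence_factors()` for any substantive analysis.
* A fixed 365-day year; leap-year error is far below the factor
  uncertainty.

Emissions are homogeneous of degree 1 in intake, factors and footprint,
which the tests assert directly.

## The synthetic-data generator

Real inputs for this kind of analysis (survey microdata, the national
recipe database) are access-restricted, so the package ships a generator
that emulates their structure with recorded ground truth:

* class fractions default to 3% pure dairy / 29% composite / 68% dairy-free
  foods;
* composite dairy content is log-uniform on 0.01–98.44 g/100 g,
  reproducing the four-orders-of-magnitude range seen in practice;
* recipes nest to a configurable depth (default 3), always acyclic by
  construction, and sum to 100 g per 100 g;
* respondents complete 1 or 2 recall days (second day with probability
  0.8), items per day are Poisson (mean 12, truncated below at 1),
  portions log-normal (median 80 g, sdlog 0.6), and survey weights are
  shift + Gamma with mean 1 — positive, mildly heterogeneous, like
  calibration weights.

Distributional shapes beyond the fractions and the dairy-content range are
conventions: no public source pins down portion or weight distributions,
so they were fixed once at values a dietary-survey analyst would call
unremarkable, and are all configurable. Ground-truth profiles are computed
with the brute-force flattener, not the production resolver, so generator
and pipeline cannot share a bug; the analytic expected per-capita intake
implied by the sampling scheme is recorded alongside the survey so
estimator output can be checked against truth.

What the generator does **not** emulate: real food descriptions and coding
idiosyncrasies, demographic structure, correlated food choices within
persons, day-of-week effects, or measurement error in recalls. Passing
tests therefore certify the *pipeline arithmetic* — resolution,
classification, weighting, conversion — not the field validity of any
particular survey.

## Problem sizes and numerical choices

The test suite runs randomized resolver-equivalence checks on databases of
up to 30 foods at depth up to 4, database-wide conservation checks at 250
foods, and parameter-recovery checks on 20 independent surveys of 2,000
respondents each (estimates required within 3 standard errors of generator
truth). These sizes give stable statistical behaviour while keeping the
whole suite under a minute of compute. Equality tolerances are 1e-12 for
algebraically exact identities and 1e-9 where sums of floating-point terms
accumulate. Ties in rounding go away from zero; empty inputs (no foods, no
persons, zero grand totals) are explicit errors or warnings, never silent
zeros.

## Known limitations

* Recipe masses are pre-cooking; nutritional (as-consumed) analyses would
  need a water-loss model this package deliberately omits.
* Bias percentages depend on the denominator convention; the package
  computes either but cannot decide which a given published figure used.
* Emissions rest on a single milk-footprint coefficient and category-level
  utilisation factors; no life-cycle allocation between dairy and beef
  co-products is attempted.
* Variance estimation ignores survey design (PSU/strata); standard errors
  from `population_mean()` describe an independent sample with the given
  weights.
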