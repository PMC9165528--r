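---
title: "Religion-sensitive food nitrogen footprint accounting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Religion-sensitive food nitrogen footprint accounting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitrofoot)
library(dplyr)
```

## The problem

Reactive nitrogen (every N species except inert N~2~) lost from the
agro-food system pollutes soil, air and water. The *food nitrogen
footprint* quantifies the reactive N released to the environment per
person and year through both the production and the consumption of food,
in kg-N · capita^-1^ · yr^-1^. In the Indian Subcontinent the footprint
is shaped by two forces this package models explicitly: the nitrogen use
efficiency (NUE) of crop cultivation, and religious dietary rules that
determine which food categories a community consumes at all.

`nitrofoot` implements the full accounting chain on long-format
food-balance-sheet (FBS) style data: cultivation N budgets → NUE →
virtual nitrogen factors (VNFs) → religion-weighted per-capita
footprints → diet/efficiency scenarios to 2050 → time-series projection
with a from-scratch LSTM recurrent cell.

## The accounting model

For a food item $m$ consumed by community $n$ in country $c$, the annual
per-capita N intake is

$$I_{mnc} = P_{mnc} \cdot \frac{365}{1000} \cdot \phi_m \cdot (1 - w_{mc}),$$

where $P$ is the protein supply in g · capita^-1^ · day^-1^, $\phi_m$
is the N content of the supplied protein (kg-N per kg protein) and
$w_{mc}$ the wasted fraction. The production footprint multiplies the
intake by the trade-considered VNF, $\mathrm{VNF}^{tr}_{mc}$; the
consumption footprint multiplies it by $(1 - d)$ with $d$ the
wastewater denitrification ratio:

$$\mathrm{NF}_c = \sum_{m}\sum_{n} W_{nc}\,
  \left( I_{mnc}\,\mathrm{VNF}^{tr}_{mc} + I_{mnc}\,(1 - d) \right),$$

with $W_{nc}$ the population share of community $n$. The default $d = 0$
reflects the absence of N-removing sewage treatment in the region, so
the consumption footprint equals the intake exactly. The regional
footprint is the unweighted mean over countries, mirrored at the
per-community level.

Five communities are modelled. Hindus are treated as lacto-vegetarians
(no meat and offal, eggs, or fish and seafood), Buddhists as vegetarians
consuming plant categories only (additionally no dairy), and Muslims,
Christians and the residual "Others" group carry no category-level
restriction. Exclusion means an excluded category contributes zero
intake for that community; by default the excluded protein is *not*
redistributed to permitted items, because national balance sheets say
nothing about compensatory consumption. `nf_config(redistribute_excluded
= TRUE)` switches on proportional redistribution for sensitivity
analysis.

### Assumptions worth stating

* Protein supplies are national: community specificity enters only
  through category exclusions (and, in scenarios, through
  community-specific share alterations). Sub-national, age- or
  gender-stratified intake is out of scope.
* Population weights are time-constant per country unless the weights
  table carries a `year` column.
* Annualization uses 365 days uniformly; leap days are ignored.

## NUE and virtual nitrogen factors

The cultivation NUE of a set of crop budgets is a pooled mass-balance
quotient,

$$\mathrm{NUE} = \frac{\sum_b N^{cont}_b}
 {\sum_b \left(N^{fert}_b + N^{man}_b + N^{adep}_b + N^{bfix}_b + N^{seed}_b\right)},$$

i.e. a *ratio of sums*, not a mean of per-crop ratios. The two statistics
differ whenever budgets differ in size; the pooled quotient is the one
consistent with mass balance (summing numerators and denominators
commutes with aggregation), so it is the implemented definition for both
within-year crop pooling and any multi-year pooling. Values above 1 are
arithmetically possible (harvested N exceeding inputs, i.e. soil N
mining) and are flagged with a warning rather than rejected.

The domestic VNF is the reciprocal chain product

$$\mathrm{VNF} = \frac{1}{\mathrm{NUE}_{cult}\cdot\mathrm{NUE}_{proc}\cdot\mathrm{NUE}_{cons}},$$

kg-N lost per kg-N in the food actually eaten, strictly decreasing in
each stage efficiency. Trade is handled by blending with the regional
average domestic factor through the self-sufficiency ratio $s$:

$$\mathrm{VNF}^{tr} = s\,\mathrm{VNF}^{dom} + (1 - s)\,\overline{\mathrm{VNF}}^{dom}_{region}.$$

Three numerical choices keep this well-behaved:

* Self-sufficiency ratios above 1 (net exporters) are clamped to 1 on
  ingest so the blend stays a convex combination and the trade factor
  always lies between its two parents.
* Animal-product chains (meat, dairy, eggs, fish) are not derived from
  feed chains — no livestock chain model is attempted — but supplied
  directly as category-level chain efficiencies in the component table.
* Decadal table values are equal-weight means of the yearly VNFs within
  the bucket. The alternative — the VNF of decade-pooled budgets — is a
  different statistic; the year-mean matches how decadal tables present
  per-decade factors, and the pooled variant remains available by
  pooling budgets before calling `cultivation_nue()`. The first decade
  bucket spans 1961–1969 because FAO series begin in 1961.

Presentation rounding is half-away-from-zero at 2 decimals
(`format_vnf_table()`), matching published decadal tables; all internal
arithmetic is full precision.

## Diet and efficiency scenarios

Four scenarios transform the 2013 baseline and hold it fixed through
2050:

| scenario | cultivation NUE | diet |
|---|---|---|
| `BAU` | 2013 values | 2013 shares |
| `NUE` | × 1.3, capped at 1 | 2013 shares |
| `EAT_LANCET` | 2013 values | shifted toward the planetary health diet |
| `INTEGRATED` | × 1.3, capped at 1 | shifted |

The 30 % efficiency gain applies to *crop* cultivation NUEs only;
animal-chain efficiencies are untouched. The cap at 1 exists because a
multiplied NUE above 1 would describe sustained soil mining as a policy
outcome. The two transformations act on disjoint inputs (production
efficiencies vs. consumption composition), so `INTEGRATED` is their
composition in either order, and applying a scenario to its own output
is the identity.

The diet shift targets the EAT–Lancet planetary health diet aggregated
to the ten categories (cereals 32, starchy roots 2, oil crops and
pulses 18, vegetables 3, fruits 5, other plant products 27, meat and
offal 4, milk and dairy 6, eggs 1, fish and seafood 2 — % of food
share). The alteration rules, per community:

* Excluded categories stay at zero; meat, eggs and fish are never
  altered for anyone (the shift is plant-side and dairy-side only).
* Milk and dairy is frozen for Muslim and Hindu communities — the
  pattern of the published alteration table, with an obvious reading for
  lacto-vegetarian Hindus whose protein depends on dairy — and treated
  as a decrease candidate for others. `scenario_spec(dairy_protected =)`
  reconfigures this.
* Any remaining category whose actual share exceeds its target by more
  than the suppression threshold (2 share points, matching the dash
  cells of whole-point tables) is decreased exactly to the target.
* The freed share is redistributed over the under-target plant
  categories proportionally to their gaps. When the inputs are whole
  points, the increases are rounded to integers by largest remainder so
  share points are conserved; otherwise exact proportional values are
  used. The increase-side cells of published tables do not follow any
  plain arithmetic rule, so only decrease-side cells are reproduced
  exactly; the redistribution rule here is an explicit, documented
  approximation.

Altered supplies are rescaled per category so the new shares hold, then
anchored: the default mode caps a community's total at the 51 g/day
adult protein reference (only over-consumers are scaled down), since the
shift is meant to be a health-compatible reduction, not a forced
increase for under-consuming communities; `"rescale"` forces the total
to the anchor and `"none"` disables it. The 2,500 kcal/day calorie
reference is carried as metadata only — the model operates on protein
mass throughout.

## Forecasting

Annual footprint series are projected with a deliberately minimal,
fully-inspectable LSTM: one univariate recurrent layer and a linear
head, no deep-learning framework. Each step applies the standard gated
recurrence — input, forget and output gates through the logistic
function, a tanh candidate — with cell update
$C_t = f_t \odot C_{t-1} + i_t \odot g_t$ and output
$h_t = o_t \odot \tanh(C_t)$, so every hidden component is strictly
inside $(-1, 1)$.

Training choices:

* Min-max scaling to $[0,1]$ is fitted on the training span only and
  inverted on outputs. A zero-variance series maps to the midpoint and
  inverts back to the constant, making a constant series a fixed point
  of fit-plus-projection.
* Full-batch gradient descent with analytic backpropagation through
  time. The step is backtracked (halved, up to 30 times) whenever it
  would increase the loss, so the recorded loss trace is non-increasing
  by construction. With backtracking making large steps safe, the
  default learning rate is 0.2 — small fixed steps (e.g. 0.01) leave the
  model visibly underfitted within the default 200 epochs, with
  one-step errors an order of magnitude above the naive last-value
  baseline on a plain linear trend.
* Defaults: window 5, hidden size 8, 200 epochs; a seed is *required*
  (there is no silent default randomness), and identical seeds give
  bit-identical fits and projections.
* Projection is recursive: each one-step prediction is fed back into
  the lag window until the horizon.
* The reported RMSE is the in-sample one-step error on the original
  scale; per-scenario RMSEs are properties of each run's series and are
  reported, not asserted.

`project_trend()` provides a deterministic damped-linear-trend
alternative for settings where stochastic training is unwanted.

## The synthetic world generator

`world_spec()` / `generate_world()` fabricate FBS-like worlds with known
ground truth so every stage is testable without external downloads.
Defaults, chosen once as regionally plausible magnitudes: six countries,
1961–2013, two supply items per category (20 items), five communities
with country-specific population mixes; per-category base protein
supplies summing to ≈ 45 g · capita^-1^ · day^-1^ in 1961 with gentle
linear growth (cereals dominant); crop cultivation NUE declining
linearly from 0.45 to 0.35 with deterministic per-country and
per-category offsets; processing and consumer NUEs 0.92 and 0.90;
category-level self-sufficiency means between 0.80 and 0.97; waste
fractions 8 % (plant) and 12 % (animal). The resulting regional
footprints sit in the 10–16 kg-N range — the right order of magnitude
for the region.

Two constructions make the ground truth exact rather than estimated:

* Budgets are reverse-engineered from the prescribed NUE trajectory:
  the input side is split across the five budget components by a
  Dirichlet draw and the harvested N is set to the target ratio times
  the input sum. The pooled quotient then recovers the true NUE exactly,
  whatever the composition draw.
* The `truth` tables (VNFs and footprints) are computed in closed form
  from the noise-free model, written as direct arithmetic that never
  calls the pipeline functions — so recovery tests compare two
  independent routes.

Noise enters only through multiplicative lognormal supply noise
(mean-one) and beta-distributed self-sufficiency ratios; at zero noise
the pipeline reproduces the closed forms to well below 10^-9^, and the
error shrinks monotonically as the noise scales shrink. All randomness
flows from one seed through per-stage subseeds, so adding a stage does
not perturb earlier draws.

What passing these tests does *not* show: the generator makes no claim
to the statistical realism of FAO series beyond trend-plus-noise (no
breaks, shocks, demographic change or price responses), so agreement on
synthetic worlds validates the accounting arithmetic and its contracts,
not any historical or projected headline value for the real region.

## Degenerate inputs and error policy

Malformed rows are rejected with row-numbered diagnostics; a zero
nitrogen-input denominator is a degenerate-budget error; a consumed
category with no VNF is an error naming the country and category (never
silently imputed — table gaps are reported via an attribute); an
alteration with freed share but no under-target plant category to
receive it is an infeasibility error. Validation tolerances: population
weights must sum to 1 within 10^-9^ per country; footprint
decompositions hold to 10^-9^; algebraic identities (VNF–NUE
reciprocity, the gated-recurrence identity) are tested to 10^-12^.

## Problem sizes

The test suite and the acceptance script run the generator at its
default scale (six countries × 53 years × 20 items), recovery and
convergence checks on 10-year worlds, scenario fixtures on 4-year
worlds, and forecaster fits on series of 25–53 points — sizes chosen so
the full suite completes in well under a minute while every code path
is exercised.

## Worked example

```{r example, eval = FALSE}
world <- generate_world(world_spec(seed = 2024))
cfg <- nf_config()

vnf_yearly <- build_vnf_table(world$budgets, world$components,
  world$supply, cfg, by = "year")
fp <- country_footprint(dplyr::filter(world$supply, year == 2013),
  vnf_yearly, world$weights, cfg)
regional_footprint(fp)

baseline <- list(supply = world$supply, budgets = world$budgets,
  components = world$components, weights = world$weights)
sapply(c("BAU", "NUE", "EAT_LANCET", "INTEGRATED"), function(nm) {
  s <- scenario_footprints(
    build_scenario_inputs(scenario_spec(nm), baseline, cfg), cfg)
  s$total_nf[s$country == "ISC average" & s$religion == "all" &
    s$year == 2050]
})
```

## Known limitations

* Only four faiths carry explicit dietary rules; adherence is binary
  and total, where real food choice is flexible.
* Livestock feed chains are not modelled; animal chain efficiencies are
  exogenous inputs.
* The EAT–Lancet reference is an adult diet; child-specific diets are
  out of scope, as are food prices, supply chains and adoption
  behaviour.
* Wastewater N removal is a single scalar ratio.
* The forecaster is a desk-scale univariate model: no exogenous
  covariates, ensembles, or uncertainty intervals.
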