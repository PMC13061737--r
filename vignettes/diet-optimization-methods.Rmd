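---
title: "Methods: multi-objective optimization of dietary guidelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-objective optimization of dietary guidelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, parameter choices and numerical
decisions behind `dietfront`, in the spirit of a statistical-methods
appendix: what is computed, under which assumptions, and what the passing
test suite does and does not demonstrate.

## From guideline to diet

A national food-based dietary guideline (FBDG) recommends daily intakes by
food group. The translation stage converts these into commodity-level
diets in three steps, each with an explicit invariant:

1. **Allocation** (`allocate_groups()`). Each group recommendation is
   split over its member commodities by fractional composition; the
   allocated intakes sum back to the group recommendation within 1e-9 g
   (mass balance, verified by `validate_mass_balance()` with a 1e-6 g
   flagging threshold — far below nutritional relevance, tight enough to
   catch logic errors).
2. **Recipe disaggregation** (`disaggregate_recipes()`). Composite foods
   are replaced by their primary ingredients using mass-fraction recipes,
   recursively until no composite remains. Resolution is a fixed-point
   iteration with a depth bound equal to the number of distinct
   composites: exceeding it implies a cyclic recipe, which is an error
   rather than silent truncation. Total mass is conserved.
3. **Imputation** (`impute_missing_nutrients()`). Missing nutrient cells
   are filled with the unweighted arithmetic mean of non-missing values
   among commodities of the same subcategory ("chemically similar foods").
   The unweighted mean was chosen over an intake-weighted one because the
   table describes commodities, not diets; imputation is idempotent and
   never touches observed cells. A subcategory with no donor is an error
   listing the (subcategory, nutrient) pairs. Protein and energy are never
   allowed to be missing: every scenario's constraints depend on them.

## Objectives and penalty

A candidate is an intake vector $Q$ (g/person/day) over eight
animal-source-food categories — beef, pork, poultry, fish, eggs, dairy,
other ruminant meat (sheep/goat), other aquatic (shellfish) — with a fixed
plant background. This eight-category decision space covers every animal
food the scenario analysis reallocates; the category list is a documented
modelling choice. Within a category, the commodity mix is held at its
guideline proportions, so category coefficients are baseline-share-weighted
means of the member commodities.

The three axes are

$$C(Q) = \sum_i Q_i R_i / 1000, \qquad
  E(Q) = \sum_i Q_i \mathrm{EF}_i / 1000, \qquad
  \mathrm{Nut}(Q) = \min_{j \in P}\ \min\!\big(\mathrm{supply}_j/\mathrm{RDA}_j,\, 1\big),$$

with producer prices $R_i$ in constant international \$/kg (PPP-adjusted,
production-side accounting), emission factors $\mathrm{EF}_i$ in kg
CO~2~e/kg under 20-year global warming potential and mass allocation, and
nutrient supplies from per-100 g densities. The nutrition score uses a
*capped minimum* over the priority set $P$: capping prevents an
over-supplied nutrient from masking a deficit in another, and the minimum
makes the score limiting-nutrient driven. For the two reference scenarios
$P$ is all four tracked micronutrients (vitamin A, vitamin B12, EPA, DHA).

Shortfalls $d_j = \max(0, \mathrm{RDA}_j - \mathrm{supply}_j)$ enter a
quadratic penalty. The deficits are normalized by their RDA before
squaring, $\mathrm{pen} = s \sum_j (d_j/\mathrm{RDA}_j)^2$: a raw
$\sum_j d_j^2$ would add squared micrograms (B12) to squared grams (EPA)
and let unit choices set the constraint pressure. The unnormalized variant
remains available (`normalize = FALSE`) for fidelity checks. The scale $s$
ramps linearly over the run, $s_0(1 + g/G)$ — a minimal "adaptive" schedule
that lets early generations explore and late generations enforce adequacy.
The base scale defaults to 1 and is exposed in `nsga_config()`; ALA is
reported in adequacy tables but not penalized, since it is abundantly
available from the plant background.

## Scenarios and constraints

Six scenarios are compiled by `build_constraints()`:

- `Baseline_FBDG` — the translated guideline diet itself, a pinned single
  point (its "bounds" are degenerate at the baseline intakes).
- `MaxProt` — every protein-containing intake scaled uniformly by
  $60/\mathrm{total}$ to the WHO 60 g/day protein reference. Uniform
  scaling is the minimal-change reading of a protein-capped reference
  diet; because it is a pure rescaling, its constraint set pins the energy
  band at the scaled diet's own energy rather than re-imposing the FBDG
  level (a proportional diet cannot satisfy both).
- Four search scenarios — `MaxVitamins`/`MaxFattyAcids`, each under the
  FBDG-native protein cap or the WHO 60 g cap — optimized by NSGA-II
  within EAT-Lancet intake ranges: red meat 0–28 g applied to the
  beef + pork + other-ruminant *sum* (the reference treats red meat as one
  composite category and no per-species split is published), poultry
  0–58 g, fish 0–100 g on the marine sum, dairy 0–500 g, eggs 0–25 g.

Two range interpretations coexist deliberately: the *ranges* above bound
the search, while the *point targets* (fish 28, pork 7, eggs 13,
poultry 29, beef 7, milk 250 g/day) are used only for compliance ratios
(`eat_lancet_ratio()`); the source framework reports both without
reconciling them, so both are kept, each in its role.

**Isocaloric constraint and plant gap-filling.** Energy is held in a
±2 % band around the FBDG energy level — a strict equality would be
numerically brittle for a real-coded search, and 2 % is well inside
day-to-day intake variation. When the search removes animal protein, plant
protein "fills the gap": each candidate gets a two-degree-of-freedom
correction, solving a 2×2 linear system for adjustments to the
protein-dense plant group (legumes/nuts) and the energy-dense group
(grains) so that total protein lands exactly on the scenario cap/target
and energy on the band center. Adjustments are clipped at zero intake;
any residual deviation counts as constraint violation. This couples the
named behaviour ("plant protein adjusts automatically") with the
isocaloric requirement through one transparent mechanism, and the
correction's cost, emissions and nutrients are fully accounted in the
objectives.

## The search

`nsga2_optimize()` is a real-coded NSGA-II: fast non-dominated sorting,
crowding distance (axes with zero span are skipped, keeping the measure
permutation-invariant on degenerate fronts), feasibility-first binary
tournaments (feasible beats infeasible; infeasible compare on violation
magnitude), simulated binary crossover (η = 15) and polynomial mutation
(η = 20) clipped to bounds — the canonical operator pair for continuous
decision spaces. Default hyperparameters are population 200, 100
generations, crossover probability 0.7, mutation probability 0.2.
Initialization is a Latin-hypercube sample with the baseline guideline
point injected, so the status quo is always represented. Penalties enter
dominance by being added to both minimized axes and subtracted from
nutrition.

Alongside the population, a bounded archive (default 800 members, pruned
by crowding) keeps every feasible non-dominated candidate encountered; the
returned front is the archive, so per-objective bests and attained
hypervolume are non-decreasing across generations. Because the penalty
ramp rescales across generations, archive members store their
base-scale penalty so candidates from different generations compare on a
common footing. All randomness flows from the single seed in
`nsga_config()`; two runs with one seed return identical fronts.

Scenario-level summaries use the front's *knee point*: the member closest
to the ideal point after min-max normalization of the three axes. A single
summary solution is needed for cross-scenario comparison tables, and the
knee point is the standard assumption when no explicit selection rule is
given.

`brute_force_pareto()` is the independent oracle: exact pairwise-dominance
enumeration of a candidate grid (≤ 10⁶ points). On 2-commodity toys the
suite checks that the search attains ≥ 95 % of the enumerated front's
hypervolume (exact 3-D hypervolume via a sweep of 2-D staircase areas) and
that every returned point lies within grid resolution of an oracle point.

## Robustness

Uncertainty is propagated multiplicatively, $p' = p(1+\varepsilon)$,
$\varepsilon \sim N(0, \sigma^2)$ with σ = 0.10 by default — proportional
noise matches how price and availability uncertainty scales. Monte Carlo
runs (default 500) each draw an independent perturbation of the selected
parameter groups (prices, emission factors, fish availability) under a
per-run seed; per-run seeds are drawn without replacement from the master
seed, giving independent, collision-free, fully reproducible streams.
Negative perturbed prices are clipped to zero with a warning. Each run
re-optimizes the scenario at a reduced budget (default population 50, 30
generations) rather than re-pricing a frozen diet, because the quantity of
interest is the stability of the *optimization solution*; the full budget
remains available through the configuration. Failures are excluded and
counted, with more than 5 % aborting the experiment.

Summaries follow the standard definitions — CV = SD/mean and the normal
approximation CI mean ± 1.96·SD/√n. The convergence check re-estimates
means at increasing run counts (default 500/1000/2000) on a *common*
nested stream, so differences isolate sample size, and applies the < 1 %
relative-difference rule. "Fish availability" is perturbed as a
multiplier on the marine upper bounds, not as a price: availability
constrains intake.

Elasticities use symmetric two-sided relative differences,
$(|\Delta Y^+| + |\Delta Y^-|)/(2\,|Y_0|\,\delta)$ at levels
δ = 5–25 %: the symmetric form is level-consistent and reduces to the
analytic log-derivative for smooth metrics (exactly 1 for a proportional
metric and 2 for a quadratic one, which the suite asserts). A zero
baseline metric yields a flagged `NA` rather than a division.

## Synthetic country archetypes

`generate_country_dataset()` emulates the statistical structure of
harmonized national datasets for four archetypes. Nutrient densities,
emission factors and prices are drawn from mean-preserving log-normal
distributions (strictly positive and right-skewed, like real composition
tables; default dispersion 0.05) around archetype means encoding the
orderings real tables show: per-kg emission factors beef > pork >
poultry ≈ fish > plant groups, per-unit-protein beef > dairy > pork; B12
and EPA/DHA confined to animal and marine foods; structural zeros stay
exactly zero under the noise.

Each dataset is calibrated so its translated diet reproduces the
archetype's FBDG protein pair exactly — totals of 85/87/85/88 g with
animal shares 0.53/0.41/0.51/0.49 for the US-, China-, Australia- and
New-Zealand-like archetypes — spanning the 0.41–0.53 animal-share band.
Egg recommendations stay at their characteristic multiples of the
EAT-Lancet point target (about 2.4× on average, up to 3.1× in the
Australia-like archetype) and the remaining animal groups absorb the
calibration uniformly. The energy target is the calibrated diet's own
energy content. Missingness is injected cell-wise at a configurable rate
(never protein or energy), with one donor per (subcategory, nutrient)
block preserved so imputation always has a precondition-satisfying input.

What the generator does *not* emulate: within-country household
heterogeneity, seasonal and temporal price/production dynamics,
correlations between prices and emission factors, and real national
composition tables. Passing tests therefore demonstrate that the
machinery is correct and calibrated on data with the assumed structure —
not that any specific national headline number is reproduced; analyses of
real countries require the corresponding national inputs.

## Problem sizes and numerical choices

The shipped demonstration (`demo_pipeline_config()`) runs all four
archetypes and six scenarios at population 100 / 60 generations, the
Monte Carlo stage at 20 runs with population 40 / 20 generations, and the
report — a few minutes on one CPU, chosen as the package's standard
desk-scale configuration. The test suite uses the same scales or smaller;
the Monte Carlo calibration checks run at n = 500–2000 where the
χ²-derived sampling band applies. Degenerate inputs are handled
explicitly: empty priority sets fall back to all tracked nutrients,
fronts of ≤ 2 points get infinite crowding everywhere, zero-variance
regressors and zero-protein diets are errors, and a search in which no
feasible candidate was ever seen returns the least-violating
non-dominated set rather than an empty front.

## Known limitations

- Protein quality (DIAAS/PDCAAS) is not modelled; plant and animal
  protein grams are treated as exchangeable, consistent with mixed-diet
  reference assumptions.
- The plant background is aggregate (4–10 groups) and only its two
  gap-filling degrees of freedom respond to the search; plant-sector
  optimization is out of scope.
- Emission factors and prices are exogenous inputs; no life-cycle
  inventory modelling is performed.
- The cost axis is production-side (PPP-adjusted producer prices), not
  consumer affordability.
- Scenario summaries depend on the knee-point convention; alternative
  selections (per-front extremes, full-front clouds) are available for
  the regression analyses via `build_report(regression_points = ...)`.
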