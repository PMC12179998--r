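---
title: "Diet scenario simulation and per-meal protein quality: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diet scenario simulation and per-meal protein quality: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietshift)
library(dplyr)
```

`dietshift` answers a population-nutrition question: if older adults shift
towards more plant-based diets, how much *usable* protein do they lose, and
what fraction of the population falls below its requirement? The package
chains four models — a food-substitution engine, a per-meal protein-quality
score, a usual-intake measurement-error model, and the EAR cut-point method —
and ships a calibrated synthetic survey generator so the whole chain is
testable without restricted survey microdata.

## Protein scoring

All protein arithmetic runs on indispensable amino acid (IAA) composition,
expressed over nine scoring groups (`iaa_names()`): His, Ile, Leu, Lys,
SAA (Met+Cys), AAA (Phe+Tyr), Thr, Trp, Val. The sulphur and aromatic pairs
are stored pre-combined because adult scoring patterns define their
requirements jointly.

Three protein quantities are computed per consumption event, meal occasion,
and person-day:

* **Total protein** is the amino-acid mass of the food,
  `grams/100 × total_aa_mg / 1000`. Amino-acid mass is used instead of
  nitrogen × 6.25 because the nitrogen conversion factor overestimates
  protein for most food groups.
* **Digestible protein** multiplies by a per-food digestibility factor in
  (0, 1], assigned at the food-group level. The factors are treated as
  opaque fractions; the package does not distinguish ileal from faecal
  coefficients.
* **Utilizable protein** applies a PDCAAS-style limiting amino-acid score
  *per meal occasion*. For a meal with digestible protein $P$ (g) and
  digestible IAA masses $a_i$ (mg), the similarity factor is

  $$ S \;=\; \min\!\left(1,\; \min_i \frac{a_i / P}{r_i}\right), $$

  where $r_i$ is the reference pattern density (mg/g protein). Utilizable
  protein is $S \times P$; the daily figure is the sum over the day's
  occasions, never a daily re-score.

Two design choices in the score were genuinely open and are worth spelling
out:

* **Pool-then-score.** Amino acids are summed over all foods of an occasion
  before scoring, so complementary proteins (lysine-poor bread with
  lysine-rich legumes) help each other within a meal but not across meals.
  The premise is physiological: IAAs can only complement each other when
  eaten within a limited time frame; surplus IAAs are oxidised. This makes
  utilizable protein superadditive under pooling, a property the test suite
  checks on random fixtures. The one-occasion window is strict, and likely
  conservative — with a wider window, vegan-scenario quality losses would
  shrink somewhat.
* **Digestible denominator.** The IAA density is taken per gram of
  *digestible* protein (digestible quantities on both axes). Scoring
  digestible IAAs against total protein would mix bases; the consistent
  reading is used and the reference pattern is configurable, so the choice
  is switchable by rescaling the pattern.

A protein-free meal is assigned similarity 1 with no limiting amino acid:
utilizable protein is 0 by multiplication, so the convention avoids 0/0
without affecting any aggregate.

The shipped reference pattern is the WHO/FAO/UNU (2007) adult scoring
pattern (mg/g protein): His 15, Ile 30, Leu 59, Lys 45, SAA 22, AAA 38,
Thr 23, Trp 6, Val 39. Surveys of this kind do not always print the exact
pattern they scored against; the default here is the package's own choice
and any pattern can be supplied via `load_reference_pattern()`.

## Scenario engine

Six scenarios are supported: `original`, `flexitarian40`, `flexitarian80`,
`pescetarian`, `vegetarian`, `vegan`. Each non-original scenario carries a
conformity flag on every food item; non-conforming consumption events are
replaced **gram-for-gram** by an alternative drawn uniformly at random from
the (dietitian-style, at most 12 entries) replacement list of the item's
food group. Grams are never altered, so total consumed mass per person-day
is conserved exactly — protein, energy and quality change only through the
composition of the substitute.

The flexitarian scenarios work in two steps: first a random 40% or 80% of
all meat-and-fish events (pooled across the dataset, sample size
`round(fraction × eligible)` with half-up rounding) is selected; then each
selected event is replaced from the *vegetarian* alternatives list, which
also serves the pescetarian and vegetarian scenarios. Three sampling
conventions were open and are fixed as follows: selection pools events
across participants (not per participant, not gram-weighted); alternatives
are drawn independently per event, so the same product consumed twice may
map to different substitutes; and a single seeded generator drives each
`apply_scenario()` call, consuming the stream in documented order
(selection first, then one draw per targeted event in dataset order), so
every run is reproducible.

## Synthetic survey generator

The generator emulates the structure of a national food-consumption survey
of community-dwelling adults aged 65–79: `n` participants (default 600,
~51% men), two non-consecutive 24-h recalls each, seven meal occasions per
day (three meals, four snack moments), survey weights (unit by default —
the synthetic population is self-representative), and a food table built
from archetypes: meat/fish (complete IAA profile, digestibility ≈ 0.93),
dairy/cheese/egg, lysine-poor cereals (bread), lysine-rich but SAA-limited
legumes, soy-based processed alternatives, and trace-animal bakery items.

Daily protein intake is generated on the log scale:
$\log Y_{ij} = \log \mu_{s(i)} + b_i + \varepsilon_{ij}$ with person effect
$b_i \sim N(0, \sigma_b^2)$ and day noise
$\varepsilon_{ij} \sim N(0, \sigma_w^2)$, where
$\sigma^2 = \log(1 + \mathrm{CV}^2)$. Defaults: per-sex median habitual
intake $\mu$ of 0.96 (men) / 0.94 (women) g/kg bw/day, between-person CV
0.22, within-person CV 0.30 — values in the range reported for protein in
repeated-recall surveys. The day's protein is allocated to occasions by
fixed shares (dinner largest at 40%), then to food categories within each
occasion; category fractions are jittered log-normally (SD 0.25) from day
to day and renormalised, so meals vary while the daily total is preserved.
Grams of each food follow from its protein density, so realised intake and
the animal-protein share are calibrated **by construction**: the
animal-category fractions are rescaled by a common multiplier (solved with
`uniroot`) until the overall animal share equals the configured target
(default 0.62). An unattainable target (e.g. 1.0, impossible while bread
and bakery remain) raises a calibration error.

The vegan replacement table deliberately includes the low-protein
substitutes a realistic substitution exercise uses — beverages with zero
protein for dairy drinks, falafel, vegan luncheon — and trace-animal bakery
items are left conforming under the vegan rules (replacing them would have
minimal impact), which is why the vegan plant-protein share lands near 99%
rather than 100%.

What the generator does **not** emulate: real food-name frequencies, mixed
dishes, seasonality, interview-mode effects, reporting error, and
correlations between energy and protein beyond what the archetype
composition implies. Its quality-loss distribution is also narrower than in
real survey data (composition varies less from day to day than real menus
do). Passing tests on generated data therefore demonstrate that the
*pipeline* behaves correctly under known conditions, not that any specific
population estimate transfers to real surveys.

## Usual intake estimation

Two recall days per person mix between-person differences with day-to-day
noise; percentiles of raw daily values overstate the spread of habitual
intake. The estimator implements the classic one-part usual-intake model:

1. transform daily values towards normality (`log` by default; `identity`
   or `boxcox` with a maximum-likelihood exponent are available);
2. decompose the variance into between-person $\hat\sigma_b^2$ and
   within-person $\hat\sigma_w^2$ components with survey-weighted one-way
   random-effects moments ($\hat\sigma_w^2$ from within-person day
   variances; $\hat\sigma_b^2$ as the variance of person means minus
   $\hat\sigma_w^2 \overline{1/n_i}$, floored at zero);
3. shrink each person's mean towards the weighted stratum mean by
   $\sqrt{\hat\sigma_b^2 / (\hat\sigma_b^2 + \hat\sigma_w^2 / n_i)}$;
4. back-transform the shrunken values into a weighted population of
   person-level usual intakes, queryable with `percentile()` and
   `prevalence_below()`.

The square-root form of the shrinkage is deliberate: it makes the variance
of the shrunken values equal $\hat\sigma_b^2$, so the estimated usual-intake
distribution carries the between-person variance and tail probabilities are
asymptotically correct. The plain reliability ratio (no square root) gives
best predictions of *individual* usual intakes but under-disperses the
*distribution*, biasing prevalence estimates towards 0/100%. Survey weights
enter the stratum mean, both variance components, and all quantiles;
weighted quantiles use a frequency-weight generalisation of R's type-7
quantile, so doubling a weight is exactly equivalent to duplicating the
person. Back-transformation is the plain inverse transform: under the log
transform the usual intake is the person-level *median* daily intake, which
matches how the generator's targets are defined. Age is not a covariate
(the population is a single 65–79 stratum); full survey estimators add age
trends and spline back-transformations, which are out of scope here.

Limitations: with only two days per person the variance decomposition is
noisy in small strata; the one-part model presumes a daily-consumed
nutrient (fine for protein, wrong for episodically consumed foods); and
negative variance estimates are floored at zero, which collapses the
distribution to the mean when within-person noise dominates.

## Adequacy against a quality-adjusted EAR

The conventional protein EAR of 0.66 g/kg bw/day presumes high-quality
protein and ignores digestibility, so it cannot be compared directly with
utilizable intake. The package re-expresses it on the utilizable scale: the
per-person-day quality loss $1 - \text{utilizable}/\text{total}$ is
computed on the **original** diet, and its weighted median $\ell$ gives

$$ \mathrm{EAR}_{\text{adj}} = 0.66 \times (1 - \ell), $$

reported rounded to two decimals (the unrounded value is retained). The
correction is multiplicative — a proportional quality discount — which is
the only reading consistent with the conventional worked example
(loss 11.9% → 0.58 g/kg, where absolute subtraction would give 0.54).
Prevalence of inadequacy is then the EAR cut-point estimate: the weighted
share of *usual* (not day-level) utilizable intakes strictly below
$\mathrm{EAR}_{\text{adj}}$; day-level values would overstate inadequacy.

## Numerical conventions and problem sizes

Amino-acid bookkeeping is in mg throughout, converted to grams only at
reporting. Ties in the limiting amino acid resolve to the first group in
the fixed IAA order. Zero-gram events are retained (they preserve the
provenance of replacements) and contribute nothing. Events referencing
unknown foods, unknown meal-occasion labels, and non-positive
digestibilities are errors, never silently repaired.

The test suite exercises the pipeline at the sizes a desk replication
needs: oracle-equivalence sweeps over 1000 random small meals against an
independent brute-force scorer (1e-9 relative agreement), 2000–3000-seed
frequency checks of the two sampling laws against their hypergeometric and
uniform expectations, 20-seed parameter-recovery runs at n = 500 (variance
components within 15% relative, median within 3%, prevalence within 3
percentage points of the analytic log-normal tail), and 10-seed end-to-end
runs checking that prevalence of inadequacy rises monotonically from
original through vegetarian to vegan, with the vegan scenario above 50%.

```{r example, eval = FALSE}
cfg <- generator_config(n_participants = 600, seed = 1)
ft  <- generate_food_table(cfg)
ds  <- generate_recalls(cfg, ft$foods)
report <- build_report(ds, ft$foods, ft$replacements, seed = 101)
report
plot_intake_by_scenario(report, per_kg = TRUE)
```
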