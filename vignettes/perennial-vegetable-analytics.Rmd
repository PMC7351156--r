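---
title: "Methods: perennial-vegetable inventory, nutrition and carbon analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perennial-vegetable inventory, nutrition and carbon analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvcrops)
```

Perennial vegetables (PVs) are perennial plants — living three or more
years and yielding more than one year of harvest — cultivated for edible
vegetative parts or savoury reproductive structures. Dessert fruits,
culinary herbs, root crops, and crops killed by harvest are outside the
definition; shrubs, trees, bamboos, palms and cacti all count as the
single growth form `woody`, alongside `vine` and `herb`. This vignette
documents the models behind the package's three analyses, the parameters
that matter, what the synthetic-data generator does and does not emulate,
and the numerical choices made where the design was open.

## Inventory accounting

A species table carries one row per cultivated species with categorical
traits validated against controlled vocabularies (`pv_levels`). Three
fields are set-valued (parts used, thermal climates, moisture regimes):
a species eaten for both leaves and flowerbuds carries both tokens,
semicolon-delimited in CSV cells.

`breakdown()` computes counts and percentages per category. Two
denominators are possible for set-valued fields, and the choice changes
the numbers:

* **multi-count** (default): a species is counted once per value, and
  percentages are over the number of *values*. This mirrors the
  convention of published form-by-part charts, where a species with two
  parts appears twice.
* **single-count** (`single_count = TRUE`): each species counts once by
  its first listed value.

The multi-count flag is recorded as an attribute so downstream reports
can state the denominator. Climate reporting optionally rolls the seven
thermal classes into three belts (tropical incl. subtropics; temperate;
boreal/arctic); a species spanning several climates within one belt
counts once per belt.

Percentages are computed at full precision and rounded only for display,
half away from zero at one decimal (`round_half_up()`). For integer
percentage summaries of small tables we use largest-remainder
apportionment to 100 (`percent_int100()`), with remainder ties going to
the smaller category; this is the only convention that reproduces the
published integer shares of both multi-nutrient species lists (62/25/13
and 58/29/13) from their raw counts, which no single per-value rounding
rule does.

`perennial_share()` returns a lower and upper bound on the perennial
fraction of vegetable crop species because perennials sometimes grown as
annuals can be counted either way: the lower bound counts only fully
perennial crops, the upper adds the perennial-as-annual group. The
perennial-as-annual distinction is a `lifecycle` value on the species
record, not a separate record.

## Nutrient concentration classes

All concentrations are per 100 g fresh weight, the standard basis for
vegetable nutrient reporting. Nine nutrients are assessed — fiber
(g/100 g), Ca, Fe, Mg, Zn, vitamin C and vitamin E (mg/100 g), vitamin A
(mg RAE/100 g), folate (mcg/100 g) — chosen for their relevance to the
two deficiency syndromes. Iodine is excluded: terrestrial plants do not
carry useful levels.

Class boundaries are anchored to a **reference set** of 22 widely grown
and marketed vegetable crops (both annual and perennial). For each
nutrient the reference range `[ref_min, ref_max]` over crops *with data*
is split into equal tertiles; below the range is very low, above it up to
twice `ref_max` is very high, and beyond twice `ref_max` is extremely
high. Design choices:

* **Tertiles of the range endpoints, not quantiles of the values.** The
  edges are `ref_min + span/3` and `ref_min + 2 span/3`. This is the only
  rule consistent with the published iron and zinc class rows.
* **Half-open intervals**, closed at `ref_max` on the high side:
  `high = [t2, ref_max]`, `very_high = (ref_max, 2 ref_max]`. Published
  two-decimal bounds with their `+0.01` offsets are display formatting
  (and are internally inconsistent between nutrients as printed); the
  package stores continuous boundaries and formats only in
  `render_table(..., "bounds")`.
* **Degenerate inputs**: fewer than two reference values is an error
  (`insufficient reference`), as is a zero-width range. A reference
  minimum of exactly 0 — the vitamin A case — disables the very-low class
  and `[0, t1)` maps to low.
* **Cassava leaf** is excludable from the reference set (default
  excluded) as an extreme outlier that would stretch every range.

`classify()` is total and monotone on `[0, Inf)`: every finite
non-negative value receives exactly one class, and larger values never
receive a lower class. Both properties are property-tested over random
bounds. "Superabundant" means very high or extremely high, i.e. above
the reference maximum.

## Meta-analysis and syndrome scoring

`aggregate_profiles()` pools multi-source measurements into unweighted
arithmetic means per species and nutrient. No inverse-variance weighting
is attempted: source variances are rarely reported in the compiled
literature, and the published species means are simple means. Dry-basis
values convert first via `fresh = dry * (1 - moisture_fraction)`; the
moisture fraction must be supplied explicitly since compilations rarely
state which moisture was assumed.

Multi-part species support two modes. `per_part` keeps one profile per
(species, part). `species_max` takes, per nutrient, the maximum across a
species' part-level means — the species-level rating used for
multi-nutrient scoring, so a crop whose best levels are split between,
say, leaves and flowerbuds is credited with each part's best. This
matches how species reach the published multi-nutrient lists through
combinations of parts.

Scoring: 3 points per extremely-high nutrient, 2 per very-high, 1 per
high, summed over the syndrome's nutrients (traditional: Fe, Zn, vitA,
folate, max 12; industrial: fiber, Ca, Mg, vitA, vitC, vitE, max 18);
6 points qualifies. Missing nutrients contribute 0 points rather than
disqualifying the species — compilations are incomplete and a species is
scored on what is known — but stay visible as `NA` in the contributing
map. The implementation is verified against exhaustive enumeration of
all 6^4 class combinations. Ranking ties in `top_n_species()` break
alphabetically; the choice is arbitrary but deterministic.

## Carbon scenarios

Adoption trends are fitted to a combined historical production-area
series (the sum of the four PV crops with long series: artichoke,
asparagus, avocado, olive; 1967–2017): ordinary least squares for the
linear curve, OLS on log(area) for the exponential, which requires
strictly positive areas. New adoption is `projected(2050) −
projected(2020)`, floored at 0, with negative projected areas clamped to
0; no explicit projection formula is prescribed by the source material,
so the difference-of-projections form is the package's choice.

The 12-scenario grid crosses curve (linear/exponential), world vegetable
area (58.2 Mha current, 174.5 Mha tripled — tripling being the estimated
growth needed to feed everyone enough vegetables) and woody share of new
adoption (25/50/75%). Tripled-area totals scale base-area totals by
174.5/58.2 ≈ 2.998, not exactly 3; published family totals can be
injected via `totals_override` to bypass the discrepancy. Sequestration
is linear accounting — `area × rate × 44/12` — with no soil-carbon
saturation or time dependence; rates are constant category averages
(defaults 3.71 MgC/ha/yr woody, 0.43 herbaceous). The 44/12 CO2/C molar
mass ratio is the package's choice of conversion; it is the unique factor
consistent with every non-woody cell of the published grid.

Two numerical points. First, `average_rate()` resolves literature rate
ranges by midpoint (or low/high) before averaging, but no policy
reproduces the published category averages exactly (midpoint gives 4.22
and 0.50 against 3.71 and 0.43), so the published averages are taken as
authoritative defaults in `seq_rates()` rather than recomputed. Second,
the grid rounds woody/non-woody allocations to its 0.1 Mha reporting
resolution *before* computing CO2: the published grid's own woody cells
are only consistent (within ~0.7%) with CO2 computed from the rounded
areas, and this choice keeps the area and CO2 columns of any rendered
report mutually consistent. One published row (1a) is internally
inconsistent beyond that and is flagged `consistent = FALSE` in the
fixture.

## Synthetic data: what it emulates and what it does not

The generators produce the three pipeline inputs under the study
conditions, with explicit seeds everywhere and no global RNG state.

**Inventory** (`inventory_spec()`): 613 species by default, categorical
fields drawn independently with the published shares where stated (form
36.5/11.7/50.9%, domestication 2.9/30.7/61.0/1.5/2.6%, 9% full and 46%
partial shade, 18.5% perennial-grown-as-annual), normalised to sum to 1.
Parts and climates have no published marginal percentages; defaults are a
leaf-dominant mix (45% leaf) and a tropics-heavy climate gradient chosen
once as field-realistic. Set-valued fields carry a second value with
probability 0.15. Fields are drawn independently, so real
trait correlations (e.g. woody species skewing tropical) are *not*
emulated; tests on marginal breakdowns are unaffected, but the generator
should not be used to study trait associations.

**Composition** (`composition_spec()`): 240 species by default. Latent
true concentrations are log-normal per nutrient — concentrations are
positive and right-skewed, and per-nutrient parameters respect the very
different scales (mcg folate vs mg Ca); the compiled data offer no
distributional information, so log-normality is a modelling convenience,
documented as such. The log-location is calibrated analytically so the
expected fraction of species with ≥ 1 superabundant nutrient hits the
target (default 64%): with `k = 9` nutrients covered independently with
probability `c = 0.8`, the per-nutrient tail probability solves
`1 − (1 − c p)^k = target`, and `mu = log(ref_max) − sigma qnorm(1 − p)`.
Monte-Carlo verification over 12 seeds gives a mean measured fraction of
0.641 at n = 240 (single draws fluctuate with binomial sd ≈ 3%).
Per-source observations jitter log-normally (sd 0.1, mean-corrected)
around the latent value, 1–3 sources per species-nutrient, 25% reported
dry-basis with moisture drawn in [0.70, 0.95] such that conversion
recovers the latent fresh value exactly. Inter-nutrient correlation
within a species is not modelled; the calibration target and marginal
classes are unaffected, but joint statistics (e.g. the share with ≥ 4
superabundant nutrients) are conservative relative to correlated real
data.

**Area series** (`series_spec()`): linear or exponential ground truth
plus additive Gaussian noise over 1967–2017; noiseless series let the
fitters recover parameters to machine precision, and a slope of 4.9/30
Mha/yr reproduces a known 4.9 Mha of 2020–2050 adoption analytically.

## Problem sizes and test design

The test suite regenerates all fixtures in code. Stochastic checks use
fixed seeds chosen a priori: trend-recovery runs 100 seeded noisy series
(slope within 3 OLS standard errors, ≥ 96/100 required),
classification properties cover 10,000 random value/bounds cases, and
the composition calibration is checked both as a single 240-species
draw (±6 points) and as a 4-seed average. The published-table fixtures
(16- and 24-row multi-nutrient lists, 12-scenario grid, class table)
are carried verbatim, inconsistencies included, and flagged where they
are known to be unreliable rather than silently corrected.

## Known limitations

* Inventory and composition generators draw traits and nutrients
  independently; real crop data are correlated.
* Sequestration is constant-rate accounting: no saturation, no
  age-structure, no soil/biomass split.
* No bioavailability or daily-requirement computation — deliberately:
  bioavailability varies with diet composition and requirements vary
  across ages and physiological states, so species are benchmarked
  against reference crops instead.
* The exponential fitter is log-linear OLS, which weights proportional
  errors; for series with zeros it is undefined and errors out rather
  than fudging an offset.
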