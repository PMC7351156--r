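# pvcrops

Analytics for **perennial vegetables (PVs)** — perennial plants cultivated
for their edible vegetative growth (leaves, shoots, petioles) or savoury
reproductive structures (flowerbuds, flowers, vegetable fruits, unripe
seeds). PVs are a large, fragmented class of crops: hundreds of cultivated
species across more than a hundred botanical families, most of them
regional and little studied. This package is for agroecologists, nutrition
researchers and food-systems modellers who want to treat that class
quantitatively. It implements three linked analyses as one tested
pipeline:

1. **Inventory** — validated species tables with categorical breakdowns
   (growth form, part used, thermal climate, moisture, shade,
   domestication status), perennial-share bounds among vegetable crops,
   and current cultivated-area accounting.
2. **Nutrition** — reference-anchored nutrient concentration classes,
   meta-analytic per-species mean profiles, and multi-nutrient scoring
   against two deficiency syndromes.
3. **Carbon** — adoption-trend fitting on historical crop-area series and
   a 12-scenario projection of carbon sequestration from new PV adoption
   to 2050.

A fully seeded synthetic-data generator produces every input the pipeline
needs (species tables, multi-source nutrient measurements, area series)
with known ground truth, so all statistical behaviour is testable.

## The models

**Concentration classes.** For each nutrient *j*, the range
[min_j, max_j] observed across a reference set of 22 widely grown and
marketed vegetables is split into tertiles:

```
very_low  = [0, min_j)          low    = [min_j, t1)
medium    = [t1, t2)            high   = [t2, max_j]
very_high = (max_j, 2 max_j]    extremely_high = (2 max_j, Inf)
```

with `t1 = min_j + (max_j - min_j)/3`, `t2 = min_j + 2(max_j - min_j)/3`.
A concentration above `max_j` is **superabundant**. Species are scored
against the *traditional malnutrition* syndrome (Fe, Zn, vitamin A,
folate; iodine excluded — terrestrial plants carry none) and the
*industrial diet* syndrome (fiber, Ca, Mg, vitamins A, C, E): 3 points
per extremely-high nutrient, 2 per very-high, 1 per high; ≥ 6 points
qualifies a *multi-nutrient crop*.

**Carbon scenarios.** New adoption `A` (Mha) by 2050 comes from linear or
exponential (log-linear OLS) trends fitted to 1967–2017 production-area
series, scaled to the assumed world vegetable area (current 58.2 Mha or
tripled 174.5 Mha). A woody fraction `f ∈ {0.25, 0.5, 0.75}` splits the
area, and annual sequestration is

```
CO2 (MMT/yr) = area (Mha) x rate (MgC/ha/yr) x 44/12
```

with category-average rates 3.71 MgC/ha/yr (woody) and 0.43 (vines and
herbs). Curve x world-area x woody-fraction gives the 12-scenario grid
`1a`–`4c`.

## Worked example

```r
library(pvcrops)

grid <- build_scenario_grid(
  totals_override = c("1" = 4.9, "2" = 8.8, "3" = 14.8, "4" = 26.4),
  rates = seq_rates(woody = 3.71, herbaceous = 0.43))
render_table(grid, "scenarios")[7, c(1, 5, 6, 7, 8, 10)]
#>   scenario woody_Mha woody_MMT_co2 nonwoody_Mha nonwoody_MMT_co2 total_MMT_co2
#> 1       3a       3.7          50.3         11.1             17.5          67.8
```

Scenario 3a (tripled world area, linear adoption, 25% woody): 14.8 Mha of
new adoption splits into 3.7 Mha woody and 11.1 Mha non-woody; the
non-woody land sequesters 17.5 MMT CO2-eq/yr.

```r
fe <- class_bounds("Fe", ref_min = 0.47, ref_max = 2.11)
fe$vh_upper
#> [1] 4.22
as.character(classify(c(1.2, 5.0), fe))
#> [1] "medium"         "extremely_high"

score_syndrome(c(Fe = "extremely_high", Zn = "very_high",
                 vitA = "very_high"), "traditional")
#> <traditional syndrome score: 7 points, qualifying>
#>   Fe: XH
#>   Zn: VH
#>   vitA: VH
```

Iron above 4.22 mg/100 g (twice the reference maximum) is extremely high;
a leaf crop with extremely high Fe and very high Zn and vitamin A scores
3 + 2 + 2 = 7 and qualifies as a multi-nutrient crop for traditional
malnutrition.

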