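---
title: "Methods: HCST tier classification and survey-weighted diet-quality analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HCST tier classification and survey-weighted diet-quality analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcstdiet)
```

## The classification model

The 2014 Health Canada Surveillance Tool (HCST) is a categorical nutrient
profiling system. Every food belonging to one of the four Eating Well with
Canada's Food Guide (EWCFG) groups — Vegetables & Fruit, Grain Products,
Milk & Alternatives, Meat & Alternatives — is assigned to one of four Tiers
by comparing its content *per reference amount* (RA, the quantity of the
food typically eaten in one sitting) against fixed thresholds:

| threshold | total fat | saturated fat | sugars | sodium |
|---|---|---|---|---|
| lower | ≤ 3 g/RA | — | ≤ 6 g/RA | ≤ 140 mg/RA |
| upper | > 10 g/RA | > 2 g/RA | > 19 g/RA | > 360 mg/RA |

A threshold is *exceeded* only by a strictly greater value; equality with a
lower threshold is compliant and equality with an upper threshold is not an
exceedance. Writing L for the number of lower thresholds exceeded and U for
the number of upper thresholds exceeded, the decision procedure evaluated in
order is:

* **Vegetables & Fruit, Grain Products** (U counts all four uppers):
  U ≥ 2 → Tier 4; U = 1 → Tier 3; L = 3 → Tier 3; L = 0 → Tier 1;
  otherwise Tier 2.
* **Milk & Alternatives, Meat & Alternatives** (U′ counts only the
  fat/sugars/sodium uppers, reflecting the higher inherent saturated fat of
  these groups): U′ ≥ 2 → Tier 4; U′ = 1 → Tier 3; saturated-fat upper
  exceeded → Tier 3; L = 3 → Tier 3; L = 0 → Tier 1; otherwise Tier 2.

Two readings of the published rules were genuinely open and are resolved as
follows. First, "Tier 2 foods do not exceed up to 2 lower thresholds" is
ambiguous about the zero-exceedance case; since Tier 1 claims L = 0, Tier 2
here means 1–2 lower exceedances with no upper exceedance. Second, the
"Step 2" adjustments (dark green and orange vegetables, legumes) are
implemented as *flags* on the classification — no published rule states how
a tier should change, so the flags propagate into the diet summary where
daily Step-2 adherence (at least one dark-green and one orange vegetable
serving) is reported, and the tier is left untouched.

Foods outside the four groups are "other" foods and beverages: saturated
and/or trans fats and oils; unsaturated fats and oils; high fat and/or
sugar foods; high-calorie (≥ 40 kcal/100 g) and low-calorie (< 40 kcal/100 g)
beverages; uncategorized items; meal replacements; supplements; and
alcoholic beverages. Any beverage containing alcohol is classified as
alcoholic *before* the energy-density split — the reports treat alcoholic
beverages as their own row, so a 43 kcal/100 g beer must not land among the
sugar-sweetened drinks. These foods carry no Food Guide servings and enter
the analysis only through the calories they contribute.

## Diet summaries

Recall items are joined to the food table and aggregated per respondent:

* **Servings** = grams consumed / grams per Food Guide serving, summed by
  group × tier; "other" foods contribute zero servings.
* **Energy by category**, whose sum reproduces total energy exactly (this
  is asserted to 1e-9 relative tolerance in the tests).
* **Compliance measure**: percent of energy from Tier 4 plus all "other"
  categories.
* **Macronutrient % energy** uses the Atwater factors 4/4/9/7 kcal/g for
  carbohydrate/protein/fat/alcohol (the source material is silent; these
  are the standard factors).
* **Nutrient densities** are amounts per 1000 kcal.
* **Glycemic index/load**: GI is assigned per food subgroup from a lookup
  table, falling back to a closely-related parent category when there is no
  direct match; foods matching neither are excluded from GI/GL only. Daily
  GL is Σ GI × carbohydrate grams / 100; daily mean GI is the
  carbohydrate-weighted mean of item GI (standard practice; an unweighted
  mean would let carbohydrate-free items distort the index).
* **Energy density** divides energy from non-beverage items by their
  weight. A beverage flag in the food table governs the exclusion so that
  milk and juices are excluded along with "other" beverages. An
  all-beverage recall leaves energy density undefined (`NA`, with a
  warning).

## Misreporting

Each respondent's Estimated Energy Requirement comes from the adult IOM
factorial equations (age in years, weight in kg, height in m):

* men: EER = 662 − 9.53·age + PA·(15.91·wt + 539.6·ht)
* women: EER = 354 − 6.91·age + PA·(9.36·wt + 726·ht)

with the PA coefficient looked up by sex and activity category (defaults
1.00/1.11/1.25/1.48 for men, 1.00/1.12/1.27/1.45 for women; the table is
configurable because published applications vary in the PAL interval
mapping). Reported energy intake below 70% of EER marks an under-reporter,
above 142% an over-reporter; both boundaries belong to the plausible band
("between 70% and 142%"). The ±1 SD gloss sometimes attached to these
numbers is treated as commentary — the fixed cutoffs are authoritative.

## Compliance quartiles and survey-weighted inference

Respondents are ranked by the compliance measure and split at
survey-weighted quartile boundaries (inverse weighted empirical CDF: the
p-quantile is the smallest observed value whose cumulative weight share
reaches p). Boundary values belong to the lower quartile, matching report
conventions of the form "Q1 ≤ 19.42%". Quartile 1 is labelled *compliers*,
quartile 4 *non-compliers*. An unweighted option exists because the
original analysis does not state which was used; weighted is the default in
a survey context. With all values identical the boundaries coincide and
everyone degenerately lands in Q1 (warned).

Standard errors use bootstrap balanced repeated replication: a statistic is
recomputed under each replicate weight vector and
SE = √(scale · mean over replicates of (θ̂ᵣ − θ̂)²), scale defaulting to 1
(configurable for designs that require, e.g., Fay adjustments). Trend tests
regress the outcome on the quartile index treated as a linear 1–4 score
(common epidemiologic practice), adjusted for age, sex and reporter status
by including them in the weighted regression; continuous outcomes use
weighted least squares, binary ones a weighted logistic model. The score
coefficient's SE comes from the replicate weights and the two-sided p-value
from the normal reference — replicate-based degrees of freedom are not
defined for this design, and with hundreds of replicates the normal
reference is the natural choice. The reporting threshold defaults to
α = 0.001. Pairwise quartile contrasts use weighted mean differences with
Bonferroni correction across the six pairs; design-based Tukey adjustment
is not well defined without the original survey software's machinery, and
this is a stated deviation.

## What the synthetic generator emulates

The generator exists so that every stage has testable ground truth without
restricted-access survey microdata.

* **Food table**: a deterministic grid of 54 foods per EWCFG group — three
  levels per thresholded nutrient (below the lower threshold, between, above
  the upper) and two saturated-fat levels — guarantees every region of the
  tier rules is populated; designed "other" foods cover every subcategory,
  with beverages on both sides of 40 kcal/100 g; additional random foods
  straddle the thresholds. Energy per 100 g is derived from the macronutrient
  composition via the 4/4/9/7 factors, which is why percent-energy
  contributions sum to 100 in generated data.
* **Recalls**: each respondent carries a latent compliance score uniform on
  (0, 1). Items are drawn from a healthy pool (Tiers 1–2) and a
  non-recommended pool (Tier 4 + "other"), with the energy split tied to
  the score, so the realized percent energy from Tier 4 + "other" rises
  monotonically with it. Planted Q1→Q4 gradients default to +400 kcal/day
  total energy, −4 g/1000 kcal fiber and +0.5 kcal/g energy density —
  directions and magnitudes in line with population findings for this kind
  of compliance contrast. Fiber is steered onto its target by topping up
  with a high-fiber leafy vegetable; energy density by diluting with a
  water-rich vegetable (the pools are denser than any target, so dilution
  is one-sided). For a uniform latent score the top-minus-bottom-quartile
  contrast of a linear outcome is 0.75 times its slope, hence the /0.75
  rescaling inside the generator.
* **Misreporting**: the reporter status is drawn from a configurable
  mixture (default 0.3/0.6/0.1 under/plausible/over) with EI/EER ratio
  ranges strictly inside each class. Height is then back-solved from the
  implied EER at a sampled BMI, age, sex and activity level (the positive
  root of the resulting quadratic), and weight = BMI·height². This makes
  recovery of the mixture *exact by construction* — a deliberate choice so
  the recovery test isolates the classification code — at the cost of
  occasionally unrealistic heights in the tails.
* **Weights**: survey weights are lognormal(0, 0.3); replicate weights are
  i.i.d. multinomial bootstrap resampling weights (main weight × resampling
  count), which are mean-preserving and reproduce the closed-form variance
  of a weighted mean. Units not drawn in a replicate have replicate weight
  zero, as in any with-replacement bootstrap.

What it does **not** emulate: real nutrient correlations within the food
supply, recipe decomposition of mixed dishes, multi-day intake variance,
seasonal structure, and the stratified multistage design behind real
replicate weights. Passing tests therefore demonstrate the correctness of
the accounting, classification and inference machinery, not distributional
realism of Canadian intakes.

## Numerical choices and problem sizes

Strictness at thresholds follows the published wording everywhere (≤/<
and > are honoured exactly; the 40 kcal/100 g beverage split is inclusive
on the high-calorie side). Quartile boundary membership is resolved to the
lower quartile. Degenerate inputs (constant outcome, all-identical
compliance values, all-beverage recalls, empty recalls) are signalled
rather than silently propagated.

The test suite exercises the statistical properties at sizes chosen to
balance power against runtime on a single CPU: truth-table equivalence on
all 216 threshold regions; partition/conservation on 20 seeded studies of
500 respondents; mixture recovery and gradient recovery at n = 2000 (20
seeds, 200 replicate weights); type-I error of the trend test from 1000
null simulations at n = 300 with 100 replicates (accepted band 3–7% at
nominal 5%); and BRR agreement with the closed-form SE of a weighted mean
at n = 1000, R = 500 within 10%. The acceptance script runs the full
pipeline at n = 2000 with 500 replicates, mirroring the replicate count of
national nutrition surveys.

## Known limitations

* The published appendix with the complete HCST cut-point tables is not
  reproduced; only the four-nutrient threshold rules and the
  saturated-fat carve-out for Milk/Meat & Alternatives are encoded.
* Mixed dishes are assumed pre-assigned to a single food group/subgroup.
* Usual-intake modelling (multi-day deattenuation) is out of scope; all
  quantities are single-recall.
* The trend test's normal reference slightly underestimates tail
  uncertainty when few replicate weights are supplied; with the default
  hundreds of replicates the calibration test holds.
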