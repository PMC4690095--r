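Package: hcstdiet
Title: Diet Quality Analysis with the Health Canada Surveillance Tool Tier System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies foods into the 2014 Health Canada Surveillance Tool
    (HCST) Tiers 1-4 within the Eating Well with Canada's Food Guide (EWCFG)
    food groups, or into the "other foods and beverages" subcategories, using
    per-reference-amount thresholds for total fat, saturated fat, sugars and
    sodium. Aggregates 24-h dietary recall records into per-respondent diet
    summaries (Food Guide servings by group and tier, energy by category,
    nutrient densities per 1000 kcal, glycemic index and load, energy
    density), classifies energy misreporting against IOM Estimated Energy
    Requirements (70%/142% cutoffs), assigns HCST compliance quartiles from
    the percentage of energy contributed by Tier 4 and "other" foods, and
    compares outcomes across quartiles with survey-weighted means, bootstrap
    replicate-weight (BRR) standard errors and weighted trend tests. Includes
    a fully deterministic synthetic-study generator (food composition table,
    recall records, respondents with bootstrap replicate weights and planted
    diet-quality gradients) so the entire pipeline is testable without
    restricted-access survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
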