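# Per-respondent diet summaries from classified 24-h recall items.

#' Food Guide servings from grams consumed
#'
#' Servings are grams consumed divided by the food's grams per Food Guide
#' serving. Foods outside the four EWCFG groups ("other" foods and
#' beverages) do not carry Food Guide servings and contribute 0.
#'
#' @param amount_g grams consumed (vector).
#' @param serving_size_g grams per Food Guide serving (vector; `NA` for
#'   other foods).
#' @param major_group food group vector.
#' @return Numeric vector of servings/day contributions.
#' @export
servings_from_amount <- function(amount_g, serving_size_g, major_group) {
  ew <- major_group %in% EWCFG_GROUPS
  if (any(ew & (is.na(serving_size_g) | serving_size_g <= 0))) {
    abort("EWCFG-group foods must have serving_size_g > 0.")
  }
  ifelse(ew, amount_g / serving_size_g, 0)
}

#' Nutrient density per 1000 kcal
#'
#' @param amount nutrient amount per day (any unit).
#' @param energy_kcal total energy intake, kcal/day; must be > 0.
#' @return `amount / energy_kcal * 1000`.
#' @export
#' @examples
#' nutrient_density(15, 1500) # 10 per 1000 kcal
nutrient_density <- function(amount, energy_kcal) {
  if (any(energy_kcal <= 0)) {
    abort("Nutrient density is undefined for energy <= 0.")
  }
  amount / energy_kcal * 1000
}

#' Glycemic load
#'
#' Glycemic index times grams of available carbohydrate, divided by 100.
#'
#' @param gi glycemic index (0-150 scale).
#' @param carb_g grams of carbohydrate.
#' @return Glycemic load (dimensionless).
#' @export
#' @examples
#' glycemic_load(50, 30) # 15
glycemic_load <- function(gi, carb_g) {
  stopifnot(all(gi >= 0, na.rm = TRUE), all(carb_g >= 0))
  gi * carb_g / 100
}

#' Assign glycemic index values by food subgroup
#'
#' Each food subgroup is matched with its glycemic index in `gi_table`; when
#' there is no direct match, the GI of the closely-related parent category
#' (the food's major group, from `fallback`) is assigned; foods matching
#' neither remain `NA` and are excluded from GI/GL aggregation (a message
#' reports how many).
#'
#' @param foods food composition table.
#' @param gi_table named numeric vector, subgroup code -> GI.
#' @param fallback optional named numeric vector, major group -> GI.
#' @return Numeric GI vector, `NA` where no value could be assigned.
#' @export
assign_gi <- function(foods, gi_table, fallback = NULL) {
  gi <- unname(gi_table[foods$subgroup])
  if (!is.null(fallback)) {
    miss <- is.na(gi)
    gi[miss] <- unname(fallback[foods$major_group[miss]])
  }
  if (anyNA(gi)) {
    inform(sprintf("%d food(s) have no direct or fallback GI; excluded from GI/GL.",
                   sum(is.na(gi))))
  }
  gi
}

#' Energy density of consumed foods, excluding beverages
#'
#' Total energy from non-beverage items divided by their total weight.
#'
#' @param energy_kcal per-item energy, kcal.
#' @param amount_g per-item grams.
#' @param is_beverage per-item beverage flag.
#' @return kcal per gram.
#' @export
energy_density <- function(energy_kcal, amount_g, is_beverage) {
  keep <- !is_beverage
  if (!any(keep)) {
    abort("Energy density is undefined for an all-beverage recall.")
  }
  sum(energy_kcal[keep]) / sum(amount_g[keep])
}

#' Summarise 24-h recalls into per-respondent diet summaries
#'
#' Joins recall items to the food composition table and its HCST
#' classification and aggregates, per respondent: Food Guide servings by
#' EWCFG group and tier; energy (kcal/day) by tier and by "other" category;
#' the percentage of energy from Tier 4 plus all "other" foods/beverages;
#' percent energy from carbohydrate, protein, fat, added sugar and alcohol
#' (4/4/9/7 kcal/g conversion); nutrient densities per 1000 kcal;
#' carbohydrate-weighted mean glycemic index and daily glycemic load; energy
#' density of foods excluding beverages; and daily Step-2 adherence (at
#' least one dark-green and one orange vegetable serving).
#'
#' @param recalls tibble of recall items (`respondent_id`, `food_id`,
#'   `amount_g`).
#' @param foods food composition table (with `gi` column, possibly `NA`).
#' @param classification result of [classify_foods()]; computed if omitted.
#' @param thresholds thresholds used if `classification` must be computed.
#' @return A tibble with one row per respondent (the diet summary). Energy
#'   by category appears as `energy_TIER1` ... `energy_ALCOHOLIC_BEVERAGE`;
#'   servings as `servings_<group>_T<tier>`.
#' @export
summarize_recalls <- function(recalls, foods,
                              classification = classify_foods(foods, thresholds),
                              thresholds = hcst_thresholds()) {
  if (nrow(recalls) == 0) abort("Empty recall table.")
  if (!all(RECALL_REQUIRED_COLS %in% names(recalls))) {
    abort("Recall table must have columns respondent_id, food_id, amount_g.")
  }
  if (!all(recalls$food_id %in% foods$food_id)) {
    bad <- which(!recalls$food_id %in% foods$food_id)
    abort(sprintf("Recall rows reference unknown food_id (rows %s%s).",
                  paste(head(bad, 5), collapse = ", "),
                  if (length(bad) > 5) ", ..." else ""))
  }
  if (any(recalls$amount_g <= 0)) abort("amount_g must be > 0.")

  items <- recalls %>%
    left_join(foods, by = "food_id") %>%
    left_join(classification[, c("food_id", "category", "step2_flag")],
              by = "food_id") %>%
    mutate(
      energy_kcal = .data$amount_g * .data$energy_kcal_per_g,
      carb_g      = .data$amount_g * .data$carb_g_per_g,
      fiber_g     = .data$amount_g * .data$fiber_g_per_g,
      protein_g   = .data$amount_g * .data$protein_g_per_g,
      fat_g       = .data$amount_g * .data$fat_g_per_g,
      satfat_g    = .data$amount_g * .data$satfat_g_per_g,
      monofat_g   = .data$amount_g * .data$monofat_g_per_g,
      polyfat_g   = .data$amount_g * .data$polyfat_g_per_g,
      added_sugar_g = .data$amount_g * .data$added_sugar_g_per_g,
      alcohol_g   = .data$amount_g * .data$alcohol_g_per_g,
      sodium_mg   = .data$amount_g * .data$sodium_mg_per_g,
      calcium_mg  = .data$amount_g * .data$calcium_mg_per_g,
      iron_mg     = .data$amount_g * .data$iron_mg_per_g,
      vitc_mg     = .data$amount_g * .data$vitc_mg_per_g,
      servings    = servings_from_amount(.data$amount_g, .data$serving_size_g,
                                         .data$major_group)
    )

  # energy by category, wide with every category present
  energy_cat <- items %>%
    group_by(.data$respondent_id, .data$category) %>%
    summarise(energy = sum(.data$energy_kcal), .groups = "drop") %>%
    mutate(category = factor(.data$category, levels = FOOD_CATEGORIES)) %>%
    tidyr::pivot_wider(names_from = "category", values_from = "energy",
                       names_prefix = "energy_", values_fill = 0,
                       names_expand = TRUE)

  # servings by group x tier
  serv <- items %>%
    filter(.data$major_group %in% EWCFG_GROUPS) %>%
    mutate(col = paste0("servings_", .data$major_group, "_T",
                        match(.data$category, TIER_LEVELS))) %>%
    group_by(.data$respondent_id, .data$col) %>%
    summarise(servings = sum(.data$servings), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "col", values_from = "servings",
                       values_fill = 0)
  serv_cols <- as.vector(t(outer(EWCFG_GROUPS, paste0("T", 1:4),
                                 function(g, t) paste0("servings_", g, "_", t))))
  for (cc in setdiff(serv_cols, names(serv))) serv[[cc]] <- 0

  gi_items <- items %>% filter(!is.na(.data$gi) & .data$carb_g > 0)
  gi_sum <- gi_items %>%
    group_by(.data$respondent_id) %>%
    summarise(
      glycemic_load = sum(.data$gi * .data$carb_g) / 100,
      mean_gi = sum(.data$gi * .data$carb_g) / sum(.data$carb_g),
      .groups = "drop"
    )

  step2 <- items %>%
    group_by(.data$respondent_id) %>%
    summarise(
      dark_green_serv = sum(.data$servings[.data$step2_flag %in% "DARK_GREEN_VEG"]),
      orange_serv     = sum(.data$servings[.data$step2_flag %in% "ORANGE_VEG"]),
      legume_serv     = sum(.data$servings[.data$step2_flag %in% "LEGUME"]),
      .groups = "drop"
    ) %>%
    mutate(step2_adherent = .data$dark_green_serv >= 1 & .data$orange_serv >= 1)

  totals <- items %>%
    group_by(.data$respondent_id) %>%
    summarise(
      total_energy_kcal = sum(.data$energy_kcal),
      total_amount_g = sum(.data$amount_g),
      carb_g = sum(.data$carb_g), fiber_g = sum(.data$fiber_g),
      protein_g = sum(.data$protein_g), fat_g = sum(.data$fat_g),
      satfat_g = sum(.data$satfat_g), monofat_g = sum(.data$monofat_g),
      polyfat_g = sum(.data$polyfat_g),
      added_sugar_g = sum(.data$added_sugar_g),
      alcohol_g = sum(.data$alcohol_g), sodium_mg = sum(.data$sodium_mg),
      calcium_mg = sum(.data$calcium_mg), iron_mg = sum(.data$iron_mg),
      vitc_mg = sum(.data$vitc_mg),
      food_energy_kcal = sum(.data$energy_kcal[!.data$is_beverage]),
      food_amount_g = sum(.data$amount_g[!.data$is_beverage]),
      .groups = "drop"
    )
  if (any(totals$total_energy_kcal <= 0)) {
    abort("Respondent(s) with non-positive total energy intake.")
  }
  all_bev <- totals$food_amount_g == 0
  if (any(all_bev)) {
    warn(sprintf("%d respondent(s) reported only beverages; energy density is NA.",
                 sum(all_bev)))
  }

  other_cols <- paste0("energy_", OTHER_CATEGORIES)
  out <- totals %>%
    left_join(energy_cat, by = "respondent_id") %>%
    left_join(serv, by = "respondent_id") %>%
    left_join(gi_sum, by = "respondent_id") %>%
    left_join(step2, by = "respondent_id") %>%
    mutate(
      across(all_of(c(serv_cols, paste0("energy_", FOOD_CATEGORIES))),
             ~ tidyr::replace_na(.x, 0)),
      energy_other = rowSums(across(all_of(other_cols))),
      pct_energy_tier4_other =
        100 * (.data$energy_TIER4 + .data$energy_other) / .data$total_energy_kcal,
      pct_energy_carb    = 100 * KCAL_PER_G[["carb"]] * .data$carb_g / .data$total_energy_kcal,
      pct_energy_protein = 100 * KCAL_PER_G[["protein"]] * .data$protein_g / .data$total_energy_kcal,
      pct_energy_fat     = 100 * KCAL_PER_G[["fat"]] * .data$fat_g / .data$total_energy_kcal,
      pct_energy_satfat  = 100 * KCAL_PER_G[["fat"]] * .data$satfat_g / .data$total_energy_kcal,
      pct_energy_added_sugar = 100 * KCAL_PER_G[["carb"]] * .data$added_sugar_g / .data$total_energy_kcal,
      pct_energy_alcohol = 100 * KCAL_PER_G[["alcohol"]] * .data$alcohol_g / .data$total_energy_kcal,
      fiber_g_per_1000kcal  = nutrient_density(.data$fiber_g, .data$total_energy_kcal),
      sodium_mg_per_1000kcal = nutrient_density(.data$sodium_mg, .data$total_energy_kcal),
      calcium_mg_per_1000kcal = nutrient_density(.data$calcium_mg, .data$total_energy_kcal),
      iron_mg_per_1000kcal  = nutrient_density(.data$iron_mg, .data$total_energy_kcal),
      vitc_mg_per_1000kcal  = nutrient_density(.data$vitc_mg, .data$total_energy_kcal),
      energy_density_kcal_per_g =
        ifelse(.data$food_amount_g > 0,
               .data$food_energy_kcal / .data$food_amount_g, NA_real_),
      glycemic_load = tidyr::replace_na(.data$glycemic_load, 0),
      step2_adherent = tidyr::replace_na(.data$step2_adherent, FALSE)
    )
  out
}
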