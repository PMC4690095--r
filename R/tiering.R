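# HCST tier classification: per-reference-amount threshold rules.

#' HCST nutrient thresholds per reference amount
#'
#' The 2014 Health Canada Surveillance Tool compares each food's nutrient
#' content per reference amount (RA) against three lower thresholds (total
#' fat, sugars, sodium) and four upper thresholds (total fat, saturated fat,
#' sugars, sodium). A food "exceeds" a threshold when its value is strictly
#' greater: the lower thresholds are inclusive bounds (a food at exactly
#' 3 g fat/RA does not exceed), and the upper thresholds are strict.
#'
#' @param lower_fat_g,lower_sugars_g,lower_sodium_mg lower thresholds per RA
#'   (defaults 3 g, 6 g, 140 mg).
#' @param upper_fat_g,upper_sugars_g,upper_sodium_mg,upper_satfat_g upper
#'   thresholds per RA (defaults 10 g, 19 g, 360 mg, 2 g).
#'
#' @return A named list of class `hcst_thresholds`.
#' @export
#' @examples
#' hcst_thresholds()
hcst_thresholds <- function(lower_fat_g = 3, lower_sugars_g = 6,
                            lower_sodium_mg = 140,
                            upper_fat_g = 10, upper_sugars_g = 19,
                            upper_sodium_mg = 360, upper_satfat_g = 2) {
  th <- list(
    lower_fat_g = lower_fat_g, lower_sugars_g = lower_sugars_g,
    lower_sodium_mg = lower_sodium_mg,
    upper_fat_g = upper_fat_g, upper_sugars_g = upper_sugars_g,
    upper_sodium_mg = upper_sodium_mg, upper_satfat_g = upper_satfat_g
  )
  if (any(vapply(th, function(x) !is.numeric(x) || length(x) != 1 || x < 0,
                 logical(1)))) {
    abort("All thresholds must be single non-negative numbers.")
  }
  if (upper_fat_g <= lower_fat_g || upper_sugars_g <= lower_sugars_g ||
      upper_sodium_mg <= lower_sodium_mg) {
    abort("Each upper threshold must be strictly greater than its lower counterpart.")
  }
  structure(th, class = "hcst_thresholds")
}

#' Threshold exceedance pattern of EWCFG-group foods
#'
#' For each food, determines which lower thresholds (total fat, sugars,
#' sodium) and which upper thresholds (total fat, saturated fat, sugars,
#' sodium) are strictly exceeded per reference amount. Threshold equality
#' never counts as exceedance.
#'
#' @param foods A food composition table (see [simulate_food_database()] for
#'   the column dictionary), restricted to the four EWCFG food groups.
#' @param thresholds An [hcst_thresholds()] object.
#'
#' @return A tibble with one row per food: logical columns `low_fat`,
#'   `low_sugars`, `low_sodium`, `up_fat`, `up_satfat`, `up_sugars`,
#'   `up_sodium`, plus counts `n_lower` and the comma-separated
#'   `lower_exceeded` / `upper_exceeded` labels.
#' @export
exceedance_pattern <- function(foods, thresholds = hcst_thresholds()) {
  vals <- foods[, c("total_fat_g_per_RA", "sat_fat_g_per_RA",
                    "sugars_g_per_RA", "sodium_mg_per_RA")]
  if (any(is.na(as.matrix(vals))) || any(as.matrix(vals) < 0)) {
    abort("Per-RA nutrient values must be non-negative and non-missing.")
  }
  out <- tibble(
    low_fat    = foods$total_fat_g_per_RA > thresholds$lower_fat_g,
    low_sugars = foods$sugars_g_per_RA   > thresholds$lower_sugars_g,
    low_sodium = foods$sodium_mg_per_RA  > thresholds$lower_sodium_mg,
    up_fat     = foods$total_fat_g_per_RA > thresholds$upper_fat_g,
    up_satfat  = foods$sat_fat_g_per_RA  > thresholds$upper_satfat_g,
    up_sugars  = foods$sugars_g_per_RA   > thresholds$upper_sugars_g,
    up_sodium  = foods$sodium_mg_per_RA  > thresholds$upper_sodium_mg
  )
  out$n_lower <- out$low_fat + out$low_sugars + out$low_sodium
  out$lower_exceeded <- paste_flags(cbind(FAT = out$low_fat,
                                          SUGARS = out$low_sugars,
                                          SODIUM = out$low_sodium))
  out$upper_exceeded <- paste_flags(cbind(FAT = out$up_fat,
                                          SATFAT = out$up_satfat,
                                          SUGARS = out$up_sugars,
                                          SODIUM = out$up_sodium))
  out
}

paste_flags <- function(m) {
  apply(m, 1, function(r) paste(colnames(m)[as.logical(r)], collapse = ","))
}

#' Assign HCST tiers within the EWCFG food groups
#'
#' Implements Step 1 of the HCST. Let L be the number of lower thresholds
#' exceeded (fat, sugars, sodium). For Vegetables & Fruit and Grain Products,
#' U counts exceedances over all four upper thresholds (fat, saturated fat,
#' sugars, sodium); for Milk & Alternatives and Meat & Alternatives, U counts
#' only fat/sugars/sodium uppers, and the saturated-fat upper is handled by a
#' dedicated Tier 3 rule (these two groups carry more inherent saturated
#' fat). The decision procedure, evaluated in order:
#'
#' * Vegetables & Fruit / Grains: U >= 2 -> Tier 4; U == 1 -> Tier 3;
#'   L == 3 -> Tier 3; L == 0 -> Tier 1; otherwise Tier 2.
#' * Milk / Meat & Alternatives: U' >= 2 -> Tier 4; U' == 1 -> Tier 3;
#'   saturated-fat upper exceeded -> Tier 3; L == 3 -> Tier 3;
#'   L == 0 -> Tier 1; otherwise Tier 2.
#'
#' @inheritParams exceedance_pattern
#' @return Character vector of `"TIER1"`..`"TIER4"`, one per food.
#' @export
classify_tier <- function(foods, thresholds = hcst_thresholds()) {
  if (!all(foods$major_group %in% EWCFG_GROUPS)) {
    abort("classify_tier() only applies to foods in the four EWCFG food groups.")
  }
  ex <- exceedance_pattern(foods, thresholds)
  veg_grain <- foods$major_group %in% c("VEG_FRUIT", "GRAIN")
  L <- ex$n_lower
  U_all <- ex$up_fat + ex$up_satfat + ex$up_sugars + ex$up_sodium
  U_3   <- ex$up_fat + ex$up_sugars + ex$up_sodium

  tier <- character(nrow(foods))
  # Vegetables & Fruit, Grain Products: satfat counts in the upper tally.
  vg <- function(U, L) {
    ifelse(U >= 2, "TIER4",
      ifelse(U == 1, "TIER3",
        ifelse(L == 3, "TIER3",
          ifelse(L == 0, "TIER1", "TIER2"))))
  }
  # Milk / Meat & Alternatives: satfat excluded from the counts; exceeding
  # only the saturated-fat upper is Tier 3.
  mm <- function(U, S, L) {
    ifelse(U >= 2, "TIER4",
      ifelse(U == 1, "TIER3",
        ifelse(S, "TIER3",
          ifelse(L == 3, "TIER3",
            ifelse(L == 0, "TIER1", "TIER2")))))
  }
  tier[veg_grain]  <- vg(U_all[veg_grain], L[veg_grain])
  tier[!veg_grain] <- mm(U_3[!veg_grain], ex$up_satfat[!veg_grain], L[!veg_grain])
  tier
}

#' Step-2 subgroup flags
#'
#' Step 2 of the HCST reflects additional EWCFG guidance: consuming at least
#' one dark green and one orange vegetable each day, and having meat
#' alternatives such as legumes often. Foods in the relevant subgroups are
#' flagged; the flag does not alter the tier. Flags propagate into the diet
#' summary so daily Step-2 adherence can be reported.
#'
#' @param foods Food composition table.
#' @return Character vector: `"DARK_GREEN_VEG"`, `"ORANGE_VEG"`, `"LEGUME"`
#'   or `NA` per food.
#' @export
apply_step2 <- function(foods) {
  flag <- rep(NA_character_, nrow(foods))
  flag[foods$subgroup == "dark_green_veg"] <- "DARK_GREEN_VEG"
  flag[foods$subgroup == "orange_veg"]     <- "ORANGE_VEG"
  flag[foods$subgroup == "legumes"]        <- "LEGUME"
  flag
}

#' Classify "other" foods and beverages not recommended in the EWCFG
#'
#' Foods outside the four EWCFG food groups are grouped into: saturated
#' and/or trans fats and oils; unsaturated fats and oils; high fat and/or
#' high sugar foods; high-calorie beverages (>= 40 kcal/100 g); low-calorie
#' beverages (< 40 kcal/100 g); uncategorized (ingredients, seasonings,
#' unprepared mixes); meal replacements; supplements; alcoholic beverages.
#' Beverages containing any alcohol are classified as alcoholic before the
#' 40 kcal/100 g energy-density split is applied; non-beverages map from
#' their subcode, falling back to `UNCATEGORIZED` (with a warning) when the
#' subcode is unknown.
#'
#' @param foods Food composition table restricted to `major_group == "OTHER"`.
#' @return Character vector of [OTHER_CATEGORIES] values.
#' @export
classify_other <- function(foods) {
  if (!all(foods$major_group == "OTHER")) {
    abort("classify_other() only applies to foods with major_group OTHER.")
  }
  out <- rep(NA_character_, nrow(foods))
  bev <- foods$is_beverage
  alc <- bev & foods$alcohol_g_per_g > 0
  out[alc] <- "ALCOHOLIC_BEVERAGE"
  out[bev & !alc] <- ifelse(foods$energy_kcal_per_100g[bev & !alc] >= 40,
                            "HIGH_CAL_BEVERAGE", "LOW_CAL_BEVERAGE")
  nb <- which(!bev)
  mapped <- unname(OTHER_SUBCODES[foods$subgroup[nb]])
  unknown <- is.na(mapped)
  if (any(unknown)) {
    warn(sprintf("%d 'other' food(s) with unresolvable subcode classified as UNCATEGORIZED.",
                 sum(unknown)))
    mapped[unknown] <- "UNCATEGORIZED"
  }
  out[nb] <- mapped
  out
}

#' Classify every food in a composition table
#'
#' Dispatches each food either through the tier rules ([classify_tier()] and
#' [apply_step2()]) for the four EWCFG food groups, or through
#' [classify_other()] for "other" foods and beverages. Every food receives
#' exactly one category.
#'
#' @inheritParams exceedance_pattern
#' @param foods Full food composition table (EWCFG groups and OTHER).
#' @return A tibble with one row per food: `food_id`, `major_group`,
#'   `subgroup`, `category` (one of [FOOD_CATEGORIES]), integer `tier`
#'   (`NA` for other foods), `lower_exceeded`, `upper_exceeded`,
#'   `step2_flag`, `is_beverage`.
#' @export
#' @examples
#' db <- simulate_food_database(simulation_config(n_respondents = 10))
#' cls <- classify_foods(db$foods)
#' table(cls$category)
classify_foods <- function(foods, thresholds = hcst_thresholds()) {
  validate_foods(foods)
  res <- tibble(
    food_id = foods$food_id,
    major_group = foods$major_group,
    subgroup = foods$subgroup,
    category = NA_character_,
    tier = NA_integer_,
    lower_exceeded = "",
    upper_exceeded = "",
    step2_flag = NA_character_,
    is_beverage = foods$is_beverage
  )
  ew <- foods$major_group %in% EWCFG_GROUPS
  if (any(ew)) {
    fe <- foods[ew, ]
    ex <- exceedance_pattern(fe, thresholds)
    res$category[ew] <- classify_tier(fe, thresholds)
    res$tier[ew] <- match(res$category[ew], TIER_LEVELS)
    res$lower_exceeded[ew] <- ex$lower_exceeded
    res$upper_exceeded[ew] <- ex$upper_exceeded
    res$step2_flag[ew] <- apply_step2(fe)
  }
  if (any(!ew)) {
    res$category[!ew] <- classify_other(foods[!ew, ])
  }
  res
}

validate_foods <- function(foods) {
  missing_cols <- setdiff(FOOD_REQUIRED_COLS, names(foods))
  if (length(missing_cols)) {
    abort(paste0("Food table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  ok_group <- foods$major_group %in% c(EWCFG_GROUPS, "OTHER")
  if (!all(ok_group)) {
    abort(paste0("Unknown major_group value(s): ",
                 paste(unique(foods$major_group[!ok_group]), collapse = ", ")))
  }
  if (any(foods$reference_amount_g <= 0)) {
    abort("reference_amount_g must be > 0 for every food.")
  }
  ew <- foods$major_group %in% EWCFG_GROUPS
  if (any(ew & (is.na(foods$serving_size_g) | foods$serving_size_g <= 0))) {
    abort("EWCFG-group foods must have serving_size_g > 0.")
  }
  per_ra <- as.matrix(foods[, c("total_fat_g_per_RA", "sat_fat_g_per_RA",
                                "sugars_g_per_RA", "sodium_mg_per_RA")])
  if (any(is.na(per_ra)) || any(per_ra < 0)) {
    abort("Per-RA nutrient values must be non-negative and non-missing.")
  }
  invisible(foods)
}
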