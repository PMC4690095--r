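# Independent scalar oracle for the tier rules, written as a literal
# transcription of the published rule text, with explicit per-tier
# predicates and precedence Tier 4 > Tier 3 > Tier 1 > Tier 2. Kept
# deliberately separate in structure from the package's vectorised
# decision procedure.
tier_oracle <- function(group, fat, satfat, sugars, sodium) {
  low <- c(fat > 3, sugars > 6, sodium > 140)
  up <- c(fat = fat > 10, satfat = satfat > 2, sugars = sugars > 19,
          sodium = sodium > 360)
  if (group %in% c("VEG_FRUIT", "GRAIN")) {
    # Tier 4: exceeds at least 2 upper thresholds for total fat, saturated
    # fat, sugars, or sodium.
    if (sum(up) >= 2) return("TIER4")
    # Tier 3: exceeds all 3 lower thresholds without exceeding any upper
    # threshold, or exceeds only one upper threshold.
    if ((all(low) && sum(up) == 0) || sum(up) == 1) return("TIER3")
  } else {
    up3 <- up[c("fat", "sugars", "sodium")]
    # Tier 4: at least 2 upper thresholds for total fat, sugars, or sodium.
    if (sum(up3) >= 2) return("TIER4")
    # Tier 3: all 3 lowers without any of these 3 uppers (irrespective of
    # saturated fat), or exactly one of these 3 uppers, or only the upper
    # saturated-fat threshold.
    if ((all(low) && sum(up3) == 0) || sum(up3) == 1) return("TIER3")
    if (up[["satfat"]] && sum(up3) == 0) return("TIER3")
  }
  # Tier 1: does not exceed any of the three lower thresholds.
  if (sum(low) == 0) return("TIER1")
  # Tier 2: 1-2 lower thresholds without exceeding any upper threshold.
  "TIER2"
}

# Minimal valid one-row food table with overridable fields.
make_food <- function(food_id = "X1", major_group = "VEG_FRUIT",
                      subgroup = "other_veg", fat = 1, satfat = 0.5,
                      sugars = 2, sodium = 50, serving_size_g = 85,
                      is_beverage = FALSE, energy_kcal_per_100g = 80,
                      carb = 0.15, fiber = 0.02, protein = 0.02,
                      fat_pg = 0.01, alcohol = 0, gi = NA_real_) {
  tibble::tibble(
    food_id = food_id, description = food_id, major_group = major_group,
    subgroup = subgroup, reference_amount_g = 100,
    serving_size_g = serving_size_g,
    total_fat_g_per_RA = fat, sat_fat_g_per_RA = satfat,
    sugars_g_per_RA = sugars, sodium_mg_per_RA = sodium,
    energy_kcal_per_100g = energy_kcal_per_100g, is_beverage = is_beverage,
    gi = gi,
    energy_kcal_per_g = energy_kcal_per_100g / 100,
    carb_g_per_g = carb, fiber_g_per_g = fiber, protein_g_per_g = protein,
    fat_g_per_g = fat_pg, satfat_g_per_g = fat_pg / 2,
    monofat_g_per_g = fat_pg / 4, polyfat_g_per_g = fat_pg / 4,
    added_sugar_g_per_g = sugars / 100, alcohol_g_per_g = alcohol,
    sodium_mg_per_g = sodium / 100, calcium_mg_per_g = 0.1,
    iron_mg_per_g = 0.005, vitc_mg_per_g = 0.05
  )
}

# 54-combination threshold-region grid for one food group: three levels
# (below lower / between / above upper) for fat, sugars and sodium, two for
# saturated fat. Values chosen away from the generator's grid.
make_grid_foods <- function(group) {
  g <- expand.grid(fat = c(1, 5, 12.5), sugars = c(2, 10, 30),
                   sodium = c(50, 200, 450), satfat = c(0.5, 3.5))
  out <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    make_food(food_id = paste0(group, "_", i), major_group = group,
              subgroup = EWCFG_SUBGROUPS[[group]][1], fat = g$fat[i],
              satfat = g$satfat[i], sugars = g$sugars[i],
              sodium = g$sodium[i])
  }))
  attr(out, "grid") <- g
  out
}

# Bootstrap replicate weights (multinomial resampling) for tests.
make_repw <- function(w, R, seed = 1) {
  withr::with_seed(seed, w * stats::rmultinom(R, length(w), rep(1, length(w))))
}

# Brute-force weighted quartile boundaries: walk the sorted values and take
# the first whose cumulative weight share reaches p.
oracle_weighted_cuts <- function(x, w, probs = c(0.25, 0.5, 0.75)) {
  o <- order(x)
  xs <- x[o]; ws <- w[o] / sum(w)
  sapply(probs, function(p) {
    acc <- 0
    for (i in seq_along(xs)) {
      acc <- acc + ws[i]
      if (acc >= p - 1e-12) return(xs[i])
    }
    xs[length(xs)]
  })
}
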