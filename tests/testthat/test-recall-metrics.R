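fixture_foods <- function() {
  dplyr::bind_rows(
    make_food("G1", major_group = "GRAIN", subgroup = "whole_grains",
              serving_size_g = 35, energy_kcal_per_100g = 200,
              carb = 0.35, fiber = 0.03, gi = 55),
    make_food("V1", subgroup = "other_veg", serving_size_g = 85,
              energy_kcal_per_100g = 60, carb = 0.10, fiber = 0.04,
              gi = NA_real_),
    make_food("M4", major_group = "MEAT_ALT", subgroup = "processed_meat",
              serving_size_g = 75, fat = 12, sodium = 400,
              energy_kcal_per_100g = 300, carb = 0, fiber = 0),
    make_food("Bhi", major_group = "OTHER", subgroup = "beverage",
              serving_size_g = NA_real_, is_beverage = TRUE,
              energy_kcal_per_100g = 44, carb = 0.11, fiber = 0, gi = 63),
    make_food("BUT", major_group = "OTHER", subgroup = "sat_fats_oils",
              serving_size_g = NA_real_, energy_kcal_per_100g = 730,
              carb = 0, fiber = 0),
    make_food("MK2", major_group = "MILK_ALT", subgroup = "fluid_milk",
              serving_size_g = 250, is_beverage = TRUE, sugars = 7,
              energy_kcal_per_100g = 64, carb = 0.05, fiber = 0, gi = 30)
  )
}

fixture_recall <- function(id = "r1") {
  tibble::tibble(
    respondent_id = id,
    food_id = c("G1", "V1", "M4", "Bhi", "BUT", "MK2"),
    amount_g = c(100, 150, 100, 500, 20, 250)
  )
}

test_that("servings are grams over serving size, zero for other foods", {
  expect_equal(servings_from_amount(150, 50, "GRAIN"), 3)
  expect_equal(servings_from_amount(200, NA, "OTHER"), 0)
  expect_equal(servings_from_amount(1e-4, 50, "VEG_FRUIT"), 2e-6)
  expect_error(servings_from_amount(100, NA, "GRAIN"), "serving_size_g")
})

test_that("nutrient density, glycemic load and energy density formulas", {
  expect_equal(nutrient_density(15, 1500), 10)
  expect_equal(nutrient_density(0, 800), 0)
  expect_equal(nutrient_density(1536, 1000), 1536)
  expect_error(nutrient_density(5, 0), "undefined")

  expect_equal(glycemic_load(50, 30), 15)
  expect_equal(glycemic_load(70, 0), 0)
  # two items: GL 15 + 7 = 22; carbohydrate-weighted GI (50*30+70*10)/40
  expect_equal(sum(glycemic_load(c(50, 70), c(30, 10))), 22)
  expect_equal(sum(c(50, 70) * c(30, 10)) / 40, 55)

  expect_equal(energy_density(c(600, 100), c(300, 200), c(FALSE, FALSE)), 1.4)
  expect_equal(energy_density(c(2000, 0), c(1000, 500), c(FALSE, TRUE)), 2)
  expect_error(energy_density(10, 500, TRUE), "all-beverage")
})

test_that("GI assignment prefers the direct subgroup, then the parent category", {
  foods <- dplyr::bind_rows(
    make_food("a", subgroup = "fruit"),
    make_food("b", subgroup = "veg_juice", is_beverage = TRUE),
    make_food("c", major_group = "MEAT_ALT", subgroup = "red_meat",
              serving_size_g = 75)
  )
  gi <- suppressMessages(
    assign_gi(foods, c(fruit = 55), fallback = c(VEG_FRUIT = 48)))
  expect_equal(gi, c(55, 48, NA))
})

test_that("a six-item recall summarises to the hand-computed table", {
  s <- suppressWarnings(summarize_recalls(fixture_recall(), fixture_foods()))
  expect_identical(nrow(s), 1L)
  expect_equal(s$total_energy_kcal, 1116)
  expect_equal(s$energy_TIER1, 290)        # G1 200 + V1 90
  expect_equal(s$energy_TIER2, 160)        # MK2 (one lower threshold)
  expect_equal(s$energy_TIER4, 300)        # processed meat
  expect_equal(s$energy_SAT_TRANS_FATS_OILS, 146)
  expect_equal(s$energy_HIGH_CAL_BEVERAGE, 220)
  expect_equal(s$pct_energy_tier4_other, 100 * 666 / 1116)
  expect_equal(s$servings_GRAIN_T1, 100 / 35)
  expect_equal(s$servings_VEG_FRUIT_T1, 150 / 85)
  expect_equal(s$servings_MEAT_ALT_T4, 100 / 75)
  expect_equal(s$servings_MILK_ALT_T2, 1)
  # energy density over non-beverage items: (200+90+300+146)/(100+150+100+20)
  expect_equal(s$energy_density_kcal_per_g, 736 / 370)
  # GI/GL exclude the fruitless V1 (no GI): carb 35, 55 and 12.5 g
  expect_equal(s$glycemic_load, (55 * 35 + 63 * 55 + 30 * 12.5) / 100)
  expect_equal(s$mean_gi, (55 * 35 + 63 * 55 + 30 * 12.5) / 102.5)
  expect_equal(s$fiber_g_per_1000kcal, (3 + 6) / 1116 * 1000)
  expect_false(s$step2_adherent)
})

test_that("unknown food ids and empty recalls are rejected", {
  expect_error(summarize_recalls(tibble::tibble(respondent_id = "r",
                                                food_id = "nope",
                                                amount_g = 10),
                                 fixture_foods()), "unknown food_id")
  expect_error(summarize_recalls(fixture_recall()[0, ], fixture_foods()),
               "Empty")
})

test_that("energy by category conserves total energy on generated recalls", {
  cfg <- simulation_config(n_respondents = 60, replicate_count = 5, seed = 21)
  db <- suppressMessages(simulate_food_database(cfg))
  pop <- simulate_population(cfg, db)
  s <- summarize_recalls(pop$recalls, db$foods)
  cat_sum <- rowSums(s[, paste0("energy_", FOOD_CATEGORIES)])
  expect_equal(cat_sum, s$total_energy_kcal, tolerance = 1e-12,
               ignore_attr = TRUE)
  # macronutrient energy shares sum to 100% (energies are 4/4/9/7-derived)
  macro <- s$pct_energy_carb + s$pct_energy_protein + s$pct_energy_fat +
    s$pct_energy_alcohol
  expect_equal(macro, rep(100, nrow(s)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("summaries are additive over concatenated recalls", {
  foods <- fixture_foods()
  a <- fixture_recall("X")[1:3, ]
  b <- fixture_recall("X")[4:6, ]
  both <- dplyr::bind_rows(a, b)
  sa <- suppressWarnings(summarize_recalls(a, foods))
  sb <- suppressWarnings(summarize_recalls(b, foods))
  s <- suppressWarnings(summarize_recalls(both, foods))
  add_cols <- c("total_energy_kcal", paste0("energy_", FOOD_CATEGORIES),
                grep("^servings_", names(s), value = TRUE))
  for (cc in add_cols) {
    expect_equal(s[[cc]], sa[[cc]] + sb[[cc]], label = cc)
  }
})

test_that("the tier-4 + other energy share is scale invariant", {
  foods <- fixture_foods()
  r1 <- fixture_recall()
  r2 <- r1
  r2$amount_g <- r2$amount_g * 3.7
  s1 <- suppressWarnings(summarize_recalls(r1, foods))
  s2 <- suppressWarnings(summarize_recalls(r2, foods))
  expect_equal(s1$pct_energy_tier4_other, s2$pct_energy_tier4_other)
  expect_equal(s1$energy_density_kcal_per_g, s2$energy_density_kcal_per_g)
})
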