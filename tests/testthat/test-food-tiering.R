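test_that("exceedance pattern uses strict inequalities on both bounds", {
  cases <- list(
    # fat, sugars, sodium, satfat, expected lower, expected upper
    list(3, 6, 140, 2, "", ""),               # equality never exceeds
    list(4, 5, 100, 1, "FAT", ""),
    list(12, 25, 100, 1, "FAT,SUGARS", "FAT,SUGARS"),
    list(10.0001, 19.0001, 360.0001, 2.0001,
         "FAT,SUGARS,SODIUM", "FAT,SATFAT,SUGARS,SODIUM")
  )
  for (cs in cases) {
    f <- make_food(fat = cs[[1]], sugars = cs[[2]], sodium = cs[[3]],
                   satfat = cs[[4]])
    ex <- exceedance_pattern(f)
    expect_identical(ex$lower_exceeded, cs[[5]])
    expect_identical(ex$upper_exceeded, cs[[6]])
  }
})

test_that("negative nutrient values are rejected", {
  f <- make_food(fat = -1)
  expect_error(exceedance_pattern(f), "non-negative")
  expect_error(classify_foods(f), "non-negative")
})

test_that("published tier examples classify as stated", {
  expect_identical(
    classify_tier(make_food(major_group = "VEG_FRUIT", fat = 2, sugars = 5,
                            sodium = 100, satfat = 0.5)), "TIER1")
  expect_identical(
    classify_tier(make_food(major_group = "GRAIN", subgroup = "whole_grains",
                            fat = 12, sugars = 25, sodium = 100, satfat = 1)),
    "TIER4")
  # milk: only the saturated-fat upper exceeded -> Tier 3
  expect_identical(
    classify_tier(make_food(major_group = "MILK_ALT", subgroup = "fluid_milk",
                            serving_size_g = 250, fat = 8, sugars = 5,
                            sodium = 100, satfat = 3)), "TIER3")
  # meat: two of the fat/sugars/sodium uppers -> Tier 4 regardless of satfat
  expect_identical(
    classify_tier(make_food(major_group = "MEAT_ALT", subgroup = "red_meat",
                            serving_size_g = 75, fat = 12, sugars = 2,
                            sodium = 400, satfat = 5)), "TIER4")
  # exactly one upper in veg/fruit -> Tier 3
  expect_identical(
    classify_tier(make_food(major_group = "VEG_FRUIT", fat = 2, sugars = 2,
                            sodium = 400, satfat = 0)), "TIER3")
  expect_error(classify_tier(make_food(major_group = "OTHER",
                                       subgroup = "beverage",
                                       serving_size_g = NA_real_)),
               "EWCFG")
})

test_that("classifier matches the literal rule oracle on all 216 threshold regions", {
  for (group in EWCFG_GROUPS) {
    foods <- make_grid_foods(group)
    g <- attr(foods, "grid")
    got <- classify_tier(foods)
    want <- vapply(seq_len(nrow(g)), function(i) {
      tier_oracle(group, g$fat[i], g$satfat[i], g$sugars[i], g$sodium[i])
    }, character(1))
    expect_identical(got, want, label = paste("group", group))
  }
})

test_that("raising any single nutrient never improves the tier", {
  set.seed(41)
  bumps <- list(fat = c("total_fat_g_per_RA", 3),
                satfat = c("sat_fat_g_per_RA", 1.5),
                sugars = c("sugars_g_per_RA", 8),
                sodium = c("sodium_mg_per_RA", 150))
  for (i in 1:120) {
    f <- make_food(major_group = sample(EWCFG_GROUPS, 1),
                   subgroup = "other_veg",
                   fat = runif(1, 0, 13), sugars = runif(1, 0, 25),
                   sodium = runif(1, 0, 450))
    f$sat_fat_g_per_RA <- runif(1, 0, min(f$total_fat_g_per_RA, 4))
    base_tier <- match(classify_tier(f), TIER_LEVELS)
    for (b in bumps) {
      f2 <- f
      f2[[b[1]]] <- f2[[b[1]]] + as.numeric(b[2])
      expect_gte(match(classify_tier(f2), TIER_LEVELS), base_tier)
    }
  }
})

test_that("upper exceedance implies lower exceedance for fat/sugars/sodium", {
  set.seed(42)
  f <- make_food()[rep(1, 200), ]
  f$food_id <- paste0("R", 1:200)
  f$total_fat_g_per_RA <- runif(200, 0, 15)
  f$sugars_g_per_RA <- runif(200, 0, 30)
  f$sodium_mg_per_RA <- runif(200, 0, 500)
  f$sat_fat_g_per_RA <- runif(200, 0, 5)
  ex <- exceedance_pattern(f)
  expect_true(all(!ex$up_fat | ex$low_fat))
  expect_true(all(!ex$up_sugars | ex$low_sugars))
  expect_true(all(!ex$up_sodium | ex$low_sodium))
})

test_that("step 2 flags the dark-green, orange and legume subgroups without retiering", {
  foods <- dplyr::bind_rows(
    make_food("A", subgroup = "dark_green_veg"),
    make_food("B", subgroup = "potatoes", fat = 12, sugars = 25), # tier 4
    make_food("C", major_group = "MEAT_ALT", subgroup = "legumes",
              serving_size_g = 75, fat = 4),
    make_food("D", subgroup = "orange_veg")
  )
  res <- classify_foods(foods)
  expect_identical(res$step2_flag, c("DARK_GREEN_VEG", NA, "LEGUME",
                                     "ORANGE_VEG"))
  expect_identical(res$category, c("TIER1", "TIER4", "TIER2", "TIER1"))
})

test_that("other foods and beverages map to their subcategories", {
  bev <- function(id, kcal100, alc = 0) {
    make_food(id, major_group = "OTHER", subgroup = "beverage",
              serving_size_g = NA_real_, is_beverage = TRUE,
              energy_kcal_per_100g = kcal100, alcohol = alc)
  }
  foods <- dplyr::bind_rows(
    bev("hi", 40), bev("lo", 39.9), bev("alc", 43, alc = 0.04),
    make_food("butter", major_group = "OTHER", subgroup = "sat_fats_oils",
              serving_size_g = NA_real_, energy_kcal_per_100g = 730),
    make_food("oil", major_group = "OTHER", subgroup = "unsat_fats_oils",
              serving_size_g = NA_real_),
    make_food("candy", major_group = "OTHER", subgroup = "high_fat_sugar",
              serving_size_g = NA_real_),
    make_food("shake", major_group = "OTHER", subgroup = "meal_replacement",
              serving_size_g = NA_real_),
    make_food("bar", major_group = "OTHER", subgroup = "supplement",
              serving_size_g = NA_real_)
  )
  expect_identical(
    classify_other(foods),
    c("HIGH_CAL_BEVERAGE", "LOW_CAL_BEVERAGE", "ALCOHOLIC_BEVERAGE",
      "SAT_TRANS_FATS_OILS", "UNSAT_FATS_OILS", "HIGH_FAT_SUGAR_FOODS",
      "MEAL_REPLACEMENT", "SUPPLEMENT"))
  mystery <- make_food("m", major_group = "OTHER", subgroup = "no_such_code",
                       serving_size_g = NA_real_)
  expect_warning(res <- classify_other(mystery), "UNCATEGORIZED")
  expect_identical(res, "UNCATEGORIZED")
})

test_that("every food receives exactly one category (partition)", {
  db <- simulate_food_database(simulation_config(n_foods = 300, seed = 11))
  res <- suppressMessages(classify_foods(db$foods))
  expect_identical(nrow(res), nrow(db$foods))
  expect_true(all(res$category %in% FOOD_CATEGORIES))
  expect_false(anyNA(res$category))
  ew <- res$major_group %in% EWCFG_GROUPS
  expect_true(all(res$category[ew] %in% TIER_LEVELS))
  expect_true(all(res$category[!ew] %in% OTHER_CATEGORIES))
})

test_that("custom thresholds shift the classification", {
  f <- make_food(fat = 4, sugars = 2, sodium = 50)   # exceeds default lower fat
  expect_identical(classify_tier(f), "TIER2")
  loose <- hcst_thresholds(lower_fat_g = 5)
  expect_identical(classify_tier(f, loose), "TIER1")
  expect_error(hcst_thresholds(lower_fat_g = 11), "strictly greater")
})
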