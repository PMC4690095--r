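test_that("the generator is fully deterministic under (seed, config)", {
  cfg <- simulation_config(n_respondents = 40, replicate_count = 6, seed = 77)
  a <- suppressMessages(simulate_food_database(cfg))
  b <- suppressMessages(simulate_food_database(cfg))
  expect_identical(a, b)
  pa <- simulate_population(cfg, a)
  pb <- simulate_population(cfg, b)
  expect_identical(pa, pb)
  cfg2 <- simulation_config(n_respondents = 40, replicate_count = 6, seed = 78)
  pc <- simulate_population(cfg2, suppressMessages(simulate_food_database(cfg2)))
  expect_false(identical(pa$recalls, pc$recalls))
})

test_that("the deterministic grid covers all four tiers in every food group", {
  db <- suppressMessages(simulate_food_database(
    simulation_config(n_foods = 54, seed = 1)))
  cls <- classify_foods(db$foods)
  grid <- cls[cls$major_group %in% EWCFG_GROUPS, ]
  for (g in EWCFG_GROUPS) {
    expect_setequal(unique(grid$category[grid$major_group == g]), TIER_LEVELS)
  }
  # every other-food subcategory except the fallback bucket is represented
  expect_true(all(setdiff(OTHER_CATEGORIES, "UNCATEGORIZED") %in%
                    cls$category))
  # beverages on both sides of the 40 kcal/100 g split
  bev <- db$foods[db$foods$is_beverage & db$foods$major_group == "OTHER" &
                    db$foods$alcohol_g_per_g == 0, ]
  expect_true(any(bev$energy_kcal_per_100g >= 40))
  expect_true(any(bev$energy_kcal_per_100g < 40))
})

test_that("generated item energy is exactly amount times energy per gram", {
  cfg <- simulation_config(n_respondents = 30, replicate_count = 4, seed = 5)
  db <- suppressMessages(simulate_food_database(cfg))
  pop <- simulate_population(cfg, db)
  epg <- setNames(db$foods$energy_kcal_per_g, db$foods$food_id)
  item_energy <- pop$recalls$amount_g * epg[pop$recalls$food_id]
  s <- summarize_recalls(pop$recalls, db$foods)
  by_resp <- tapply(item_energy, pop$recalls$respondent_id, sum)
  expect_equal(as.numeric(by_resp[s$respondent_id]), s$total_energy_kcal,
               tolerance = 1e-12)
  expect_true(all(pop$recalls$amount_g > 0))
})

test_that("generated studies satisfy the io layer and round-trip through CSV", {
  cfg <- simulation_config(n_respondents = 30, replicate_count = 6, seed = 19)
  td <- withr::local_tempdir()
  gen <- suppressMessages(simulate_study(cfg, td))
  st <- suppressMessages(read_study(td))
  expect_identical(st$exclusions[["underage"]], 0L)
  expect_identical(sum(!st$respondents$in_compliance_sample), 0L)
  expect_equal(as.data.frame(st$recalls), as.data.frame(gen$recalls),
               tolerance = 1e-12)
  num_cols <- names(gen$fooddb$foods)[vapply(gen$fooddb$foods, is.numeric,
                                             logical(1))]
  expect_equal(as.data.frame(st$foods[, num_cols]),
               as.data.frame(gen$fooddb$foods[, num_cols]),
               tolerance = 1e-12)
  expect_identical(st$truth$truth$intended_status,
                   gen$truth$intended_status)
})

test_that("tie_fraction produces exact ties in the compliance measure", {
  cfg <- simulation_config(n_respondents = 40, replicate_count = 4, seed = 23,
                           tie_fraction = 0.25)
  db <- suppressMessages(simulate_food_database(cfg))
  pop <- simulate_population(cfg, db)
  s <- summarize_recalls(pop$recalls, db$foods)
  expect_gte(max(table(round(s$pct_energy_tier4_other, 10))), 10)
})

test_that("infeasible planted energy gradients are rejected", {
  expect_error(simulation_config(energy_base_kcal = 300),
               "negative energies")
})

test_that("a zero-effect configuration yields null trend p-values", {
  pvals <- sapply(1:10, function(s) {
    cfg <- simulation_config(
      n_respondents = 250, replicate_count = 60, seed = 100 + s,
      planted_effects = list(energy_kcal = 0, fiber_g_per_1000kcal = 0,
                             energy_density_kcal_per_g = 0))
    db <- suppressMessages(simulate_food_database(cfg))
    pop <- simulate_population(cfg, db)
    su <- summarize_recalls(pop$recalls, db$foods)
    su <- su[match(pop$respondents$respondent_id, su$respondent_id), ]
    qa <- assign_quartiles(su$pct_energy_tier4_other,
                           pop$respondents$survey_weight)
    trend_test(su$total_energy_kcal, qa$quartile,
               pop$respondents$survey_weight,
               replicate_weight_matrix(pop$respondents))$p_value
  })
  # under the null, small p-values should be rare and large ones present
  expect_lte(sum(pvals < 0.05), 3)
  expect_gt(max(pvals), 0.2)
})
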