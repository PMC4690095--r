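# Deterministic synthetic-study generator: food composition table, 24-h
# recall records and respondents with bootstrap replicate weights and known
# (planted) diet-quality gradients.

#' Configuration for the synthetic-study generator
#'
#' The generator plants known structure so that every pipeline stage can be
#' tested against ground truth: a latent compliance score per respondent
#' drives the percentage of energy from Tier 4 + "other" foods, total
#' energy, fiber density and energy density; the misreporting mixture fixes
#' the EI/EER ratio distribution; replicate weights are i.i.d. multinomial
#' bootstrap resampling weights.
#'
#' @param n_respondents number of respondents (default 2000).
#' @param n_foods total foods in the composition table. At least the
#'   216-food deterministic threshold grid (54 per EWCFG group), the
#'   designed "other" foods and the two adjustment foods are always
#'   generated; extra foods up to `n_foods` are drawn at random per
#'   subgroup with nutrients straddling both thresholds.
#' @param seed integer seed; fully determines all output.
#' @param misreporting_mixture proportions (under, plausible, over); must
#'   sum to 1.
#' @param ratio_ranges target EI/EER ratio ranges per reporter class,
#'   strictly inside the 70%/142% cutoffs' respective intervals.
#' @param planted_effects Q1 -> Q4 gradients: total energy (kcal/day),
#'   fiber density (g/1000 kcal) and energy density (kcal/g).
#' @param replicate_count number of bootstrap replicate weight vectors.
#' @param tie_fraction fraction of respondents given byte-identical recalls
#'   (exact ties in the compliance measure).
#' @param pct_base,pct_spread centre and latent range of the proportion of
#'   energy from Tier 4 + "other" foods.
#' @param energy_base_kcal,fiber_base,energy_density_base centres of the
#'   planted outcome distributions.
#' @param energy_sd,fiber_sd,pct_sd,ed_sd respondent-level noise.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_respondents = 2000, n_foods = 300, seed = 1,
                              misreporting_mixture = c(under = 0.3,
                                                       plausible = 0.6,
                                                       over = 0.1),
                              ratio_ranges = list(under = c(0.55, 0.68),
                                                  plausible = c(0.72, 1.40),
                                                  over = c(1.44, 1.60)),
                              planted_effects = list(
                                energy_kcal = 400,
                                fiber_g_per_1000kcal = -4,
                                energy_density_kcal_per_g = 0.5),
                              replicate_count = 500, tie_fraction = 0,
                              pct_base = 0.32, pct_spread = 0.45,
                              energy_base_kcal = 2100, fiber_base = 9,
                              energy_density_base = 1.55,
                              energy_sd = 120, fiber_sd = 0.8,
                              pct_sd = 0.02, ed_sd = 0.08) {
  if (abs(sum(misreporting_mixture) - 1) > 1e-9) {
    abort("misreporting_mixture proportions must sum to 1.")
  }
  if (n_foods < 54) abort("n_foods must be at least 54.")
  if (replicate_count < 2) abort("replicate_count must be at least 2.")
  # Infeasible gradient: the planted energy gradient must not drive any
  # respondent's target energy non-positive.
  min_e <- energy_base_kcal - abs(planted_effects$energy_kcal) / 0.75 / 2 -
    6 * energy_sd
  if (min_e <= 0) abort("Planted energy gradient implies negative energies.")
  structure(as.list(environment()), class = "simulation_config")
}

# Adjustment foods with known ids: a high-fiber leafy vegetable used to hit
# planted fiber-density targets, and a water-rich vegetable used to dilute
# energy density down to its target.
FIBER_FOOD_ID <- "F_FIBER"
WATER_FOOD_ID <- "F_WATER"

#' Generate a synthetic food composition table
#'
#' Builds (1) a deterministic grid of 54 foods per EWCFG food group -- every
#' combination of below-lower / between / above-upper levels for fat, sugars
#' and sodium and two saturated-fat levels -- so all tier-rule regions are
#' covered; (2) a designed set of "other" foods spanning every other-food
#' subcategory, with beverages on both sides of the 40 kcal/100 g split;
#' (3) the two adjustment foods; and (4) random foods per subgroup with
#' per-RA nutrients straddling the thresholds, up to `n_foods`. Energy per
#' 100 g is derived from the 4/4/9/7 kcal/g macronutrient factors, so
#' macronutrient percent-energy contributions sum to 100. A glycemic-index
#' table by subgroup is included with deliberate gaps exercising the
#' parent-category fallback.
#'
#' @param config a [simulation_config()].
#' @return List: `foods` (composition tibble), `gi_table` (named GI vector
#'   by subgroup), `gi_fallback` (named GI vector by major group).
#' @export
simulate_food_database <- function(config = simulation_config()) {
  withr::with_seed(config$seed, build_food_database(config))
}

build_food_database <- function(config) {
  grid1 <- expand.grid(fat = c(1.5, 6, 12), sugars = c(3, 12, 25),
                       sodium = c(70, 250, 500), satfat = c(1, 3),
                       KEEP.OUT.ATTRS = FALSE)
  grid <- do.call(rbind, lapply(EWCFG_GROUPS, function(g) {
    out <- grid1
    out$major_group <- g
    out$subgroup <- rep_len(EWCFG_SUBGROUPS[[g]], nrow(out))
    out
  }))

  n_extra <- max(0, config$n_foods - nrow(grid) - 14 - 2)
  if (n_extra > 0) {
    all_sub <- unlist(lapply(EWCFG_GROUPS,
                             function(g) paste(g, EWCFG_SUBGROUPS[[g]], sep = ":")))
    pick <- sample(all_sub, n_extra, replace = TRUE)
    rnd <- data.frame(
      fat = runif(n_extra, 0, 14),
      sugars = runif(n_extra, 0, 25),
      sodium = runif(n_extra, 0, 500),
      satfat = NA_real_,
      major_group = sub(":.*", "", pick),
      subgroup = sub(".*:", "", pick)
    )
    rnd$satfat <- runif(n_extra, 0, pmin(rnd$fat, 4))
    grid <- rbind(grid, rnd)
  }

  starch <- c(VEG_FRUIT = 8, GRAIN = 40, MILK_ALT = 5, MEAT_ALT = 1)
  protein <- c(VEG_FRUIT = 2, GRAIN = 7, MILK_ALT = 8, MEAT_ALT = 20)
  serving <- c(VEG_FRUIT = 85, GRAIN = 35, MILK_ALT = 250, MEAT_ALT = 75)
  g <- grid$major_group
  th <- hcst_thresholds()
  s_count <- (grid$fat > th$lower_fat_g) + (grid$sugars > th$lower_sugars_g) +
    (grid$sodium > th$lower_sodium_mg) + (grid$fat > th$upper_fat_g) +
    (grid$satfat > th$upper_satfat_g) + (grid$sugars > th$upper_sugars_g) +
    (grid$sodium > th$upper_sodium_mg)

  carb_ra <- grid$sugars + starch[g]
  prot_ra <- protein[g]
  fat_pg <- grid$fat / 100
  satfat_pg <- pmin(grid$satfat, grid$fat) / 100
  energy_pg <- (4 * carb_ra + 4 * prot_ra) / 100 + 9 * fat_pg
  fiber_density <- pmax(0.5, 6.5 - 1.0 * s_count + rnorm(nrow(grid), 0, 0.4))
  micro_scale <- pmax(0.2, 1 - 0.08 * s_count)

  ew <- tibble(
    food_id = sprintf("F%04d", seq_len(nrow(grid))),
    description = paste0(tolower(g), " ", grid$subgroup, " #",
                         seq_len(nrow(grid))),
    major_group = g,
    subgroup = grid$subgroup,
    reference_amount_g = 100,
    serving_size_g = unname(serving[g]),
    total_fat_g_per_RA = grid$fat,
    sat_fat_g_per_RA = grid$satfat,
    sugars_g_per_RA = grid$sugars,
    sodium_mg_per_RA = grid$sodium,
    is_beverage = grid$subgroup %in% c("veg_juice", "fruit_juice", "fluid_milk"),
    energy_kcal_per_g = energy_pg,
    carb_g_per_g = carb_ra / 100,
    fiber_g_per_g = fiber_density * energy_pg / 1000,
    protein_g_per_g = prot_ra / 100,
    fat_g_per_g = fat_pg,
    satfat_g_per_g = satfat_pg,
    monofat_g_per_g = 0.5 * pmax(fat_pg - satfat_pg, 0),
    polyfat_g_per_g = 0.5 * pmax(fat_pg - satfat_pg, 0),
    added_sugar_g_per_g = grid$sugars / 100,
    alcohol_g_per_g = 0,
    sodium_mg_per_g = grid$sodium / 100,
    calcium_mg_per_g = ifelse(g == "MILK_ALT", 1.2, 0.15) * micro_scale,
    iron_mg_per_g = c(VEG_FRUIT = 0.006, GRAIN = 0.015, MILK_ALT = 0.002,
                      MEAT_ALT = 0.025)[g] * micro_scale,
    vitc_mg_per_g = ifelse(g == "VEG_FRUIT", 0.4, 0.02) * micro_scale
  )
  ew$energy_kcal_per_100g <- 100 * ew$energy_kcal_per_g

  other <- other_foods_table()
  adjust <- adjustment_foods_table()
  foods <- bind_rows(ew, other, adjust)
  foods$gi <- NA_real_

  gi_table <- c(
    fruit = 55, fruit_juice = 50, potatoes = 80, other_veg = 45,
    dark_green_veg = 32, orange_veg = 50,
    whole_grains = 55, enriched_grains = 70,
    fluid_milk = 30, yogurt = 35,
    legumes = 30, nuts_seeds = 25,
    beverage = 63, high_fat_sugar = 60, meal_replacement = 55, supplement = 55
  )
  # deliberate gaps: veg_juice, other_grains, milk_other resolve through the
  # parent category; cheese/meat subgroups have no GI (carbohydrate-free).
  gi_fallback <- c(VEG_FRUIT = 48, GRAIN = 65, MILK_ALT = 33)
  foods$gi <- assign_gi(foods, gi_table, gi_fallback)

  list(foods = foods, gi_table = gi_table, gi_fallback = gi_fallback)
}

other_food_row <- function(id, desc, subgroup, bev, carb, sugar, fiber, prot,
                           fat, satfat, alc = 0, sodium = 0.5) {
  energy <- 4 * carb + 4 * prot + 9 * fat + 7 * alc
  tibble(
    food_id = id, description = desc, major_group = "OTHER",
    subgroup = subgroup, reference_amount_g = 100,
    serving_size_g = NA_real_,
    total_fat_g_per_RA = 100 * fat, sat_fat_g_per_RA = 100 * satfat,
    sugars_g_per_RA = 100 * sugar, sodium_mg_per_RA = 100 * sodium,
    is_beverage = bev,
    energy_kcal_per_g = energy, carb_g_per_g = carb, fiber_g_per_g = fiber,
    protein_g_per_g = prot, fat_g_per_g = fat, satfat_g_per_g = satfat,
    monofat_g_per_g = 0.5 * max(fat - satfat, 0),
    polyfat_g_per_g = 0.5 * max(fat - satfat, 0),
    added_sugar_g_per_g = sugar, alcohol_g_per_g = alc,
    sodium_mg_per_g = sodium, calcium_mg_per_g = 0.05,
    iron_mg_per_g = 0.003, vitc_mg_per_g = 0,
    energy_kcal_per_100g = 100 * energy
  )
}

other_foods_table <- function() {
  bind_rows(
    other_food_row("O001", "butter", "sat_fats_oils", FALSE,
                   0, 0, 0, 0.01, 0.81, 0.51),
    other_food_row("O002", "vegetable oil blend", "unsat_fats_oils", FALSE,
                   0, 0, 0, 0, 1.00, 0.10),
    other_food_row("O003", "milk chocolate", "high_fat_sugar", FALSE,
                   0.55, 0.50, 0.02, 0.05, 0.30, 0.18),
    other_food_row("O004", "hard candy", "high_fat_sugar", FALSE,
                   0.95, 0.90, 0, 0, 0, 0),
    other_food_row("O005", "cola", "beverage", TRUE,
                   0.106, 0.106, 0, 0, 0, 0, sodium = 0.04),
    other_food_row("O006", "sweetened drink at boundary", "beverage", TRUE,
                   0.10, 0.10, 0, 0, 0, 0, sodium = 0.04),
    other_food_row("O007", "diet soda", "beverage", TRUE,
                   0.002, 0.002, 0, 0, 0, 0, sodium = 0.04),
    other_food_row("O008", "light juice drink", "beverage", TRUE,
                   0.075, 0.07, 0, 0, 0, 0, sodium = 0.02),
    other_food_row("O009", "beer", "beverage", TRUE,
                   0.030, 0.005, 0, 0.005, 0, 0, alc = 0.039),
    other_food_row("O010", "red wine", "beverage", TRUE,
                   0.026, 0.006, 0, 0.001, 0, 0, alc = 0.105),
    other_food_row("O011", "instant breakfast powder", "meal_replacement",
                   FALSE, 0.66, 0.40, 0.02, 0.20, 0.05, 0.02),
    other_food_row("O012", "energy bar", "supplement", FALSE,
                   0.60, 0.35, 0.04, 0.20, 0.15, 0.05),
    other_food_row("O013", "bouillon cube", "uncategorized", FALSE,
                   0.15, 0.02, 0, 0.15, 0.05, 0.02, sodium = 240),
    other_food_row("O014", "seasoning mix", "uncategorized", FALSE,
                   0.40, 0.05, 0.05, 0.10, 0.05, 0.01, sodium = 80)
  )
}

adjustment_foods_table <- function() {
  # Tier 1 vegetables used to hit planted fiber and energy-density targets.
  leafy <- tibble(
    food_id = FIBER_FOOD_ID, description = "leafy greens mix (fiber carrier)",
    major_group = "VEG_FRUIT", subgroup = "dark_green_veg",
    reference_amount_g = 100, serving_size_g = 85,
    total_fat_g_per_RA = 0.3, sat_fat_g_per_RA = 0.05,
    sugars_g_per_RA = 1, sodium_mg_per_RA = 25, is_beverage = FALSE,
    carb_g_per_g = 0.04, fiber_g_per_g = 0.06, protein_g_per_g = 0.025,
    fat_g_per_g = 0.003, satfat_g_per_g = 0.0005,
    monofat_g_per_g = 0.001, polyfat_g_per_g = 0.001,
    added_sugar_g_per_g = 0.01, alcohol_g_per_g = 0,
    sodium_mg_per_g = 0.25, calcium_mg_per_g = 0.8, iron_mg_per_g = 0.02,
    vitc_mg_per_g = 0.5
  )
  watery <- tibble(
    food_id = WATER_FOOD_ID, description = "cucumber and celery mix",
    major_group = "VEG_FRUIT", subgroup = "other_veg",
    reference_amount_g = 100, serving_size_g = 85,
    total_fat_g_per_RA = 0.1, sat_fat_g_per_RA = 0.02,
    sugars_g_per_RA = 1.5, sodium_mg_per_RA = 15, is_beverage = FALSE,
    carb_g_per_g = 0.022, fiber_g_per_g = 0.005, protein_g_per_g = 0.003,
    fat_g_per_g = 0.001, satfat_g_per_g = 0.0002,
    monofat_g_per_g = 0.0004, polyfat_g_per_g = 0.0004,
    added_sugar_g_per_g = 0.015, alcohol_g_per_g = 0,
    sodium_mg_per_g = 0.15, calcium_mg_per_g = 0.2, iron_mg_per_g = 0.003,
    vitc_mg_per_g = 0.03
  )
  out <- bind_rows(leafy, watery)
  out$energy_kcal_per_g <- 4 * out$carb_g_per_g + 4 * out$protein_g_per_g +
    9 * out$fat_g_per_g
  out$energy_kcal_per_100g <- 100 * out$energy_kcal_per_g
  out
}

#' Generate a synthetic respondent population with recalls and ground truth
#'
#' Each respondent carries a latent compliance score (uniform on 0-1). The
#' score drives the target proportion of energy from Tier 4 + "other" foods,
#' and the planted total-energy, fiber-density and energy-density gradients.
#' Recall items are drawn from two food pools (healthy: Tiers 1-2;
#' non-recommended: Tier 4 plus "other" categories) with energy allocations
#' mixing by the score, then adjusted with the fiber-carrier and water-rich
#' vegetable foods to hit the fiber and energy-density targets. The EI/EER
#' ratio is drawn from the misreporting mixture and respondent height/weight
#' are back-solved (at a sampled BMI) so that each respondent's true reporter
#' status is exact. Survey weights are lognormal; replicate weights are
#' i.i.d. multinomial bootstrap resampling weights (mean-preserving; zero
#' for units not resampled in a replicate).
#'
#' @param config a [simulation_config()].
#' @param fooddb result of [simulate_food_database()]; regenerated from
#'   `config` if omitted.
#' @return List: `respondents` (tibble incl. `repw_1..R` columns), `recalls`
#'   (tibble `respondent_id`, `food_id`, `amount_g`), `truth` (latent
#'   scores, targets and intended status per respondent, plus the quartile
#'   gradients planted).
#' @export
simulate_population <- function(config = simulation_config(),
                                fooddb = simulate_food_database(config)) {
  withr::with_seed(config$seed + 1L, build_population(config, fooddb))
}

build_population <- function(config, fooddb) {
  foods <- fooddb$foods
  cls <- classify_foods(foods)
  epg <- setNames(foods$energy_kcal_per_g, foods$food_id)
  fpg <- setNames(foods$fiber_g_per_g, foods$food_id)

  adj_ids <- c(FIBER_FOOD_ID, WATER_FOOD_ID)
  healthy_solid <- foods$food_id[cls$category %in% c("TIER1", "TIER2") &
                                   !cls$is_beverage &
                                   foods$energy_kcal_per_g >= 1.0 &
                                   !foods$food_id %in% adj_ids]
  healthy_bev <- foods$food_id[cls$category %in% c("TIER1", "TIER2") &
                                 cls$is_beverage]
  bad_solid <- foods$food_id[(cls$category == "TIER4" |
                                cls$category %in% OTHER_CATEGORIES) &
                               !cls$is_beverage &
                               foods$energy_kcal_per_g >= 2.5]
  bad_bev <- foods$food_id[cls$category %in% c("HIGH_CAL_BEVERAGE",
                                               "ALCOHOLIC_BEVERAGE")]
  low_bev <- foods$food_id[cls$category == "LOW_CAL_BEVERAGE" &
                             foods$energy_kcal_per_g >= 0.2]
  for (pool in list(healthy_solid, healthy_bev, bad_solid, bad_bev, low_bev)) {
    if (length(pool) == 0) abort("Food database lacks a required food pool.")
  }

  n <- config$n_respondents
  u <- runif(n)
  pe <- config$planted_effects
  # Q1 -> Q4 contrast of a linear-in-u outcome is 0.75 * slope for uniform u.
  p_target <- pmin(0.90, pmax(0.02,
    config$pct_base + config$pct_spread * (u - 0.5) + rnorm(n, 0, config$pct_sd)))
  e_target <- config$energy_base_kcal +
    pe$energy_kcal / 0.75 * (u - 0.5) + rnorm(n, 0, config$energy_sd)
  if (any(e_target <= 100)) abort("Planted energy gradient produced non-positive energies.")
  f_target <- pmax(0.5, config$fiber_base +
    pe$fiber_g_per_1000kcal / 0.75 * (u - 0.5) + rnorm(n, 0, config$fiber_sd))
  d_target <- pmax(0.4, config$energy_density_base +
    pe$energy_density_kcal_per_g / 0.75 * (u - 0.5) + rnorm(n, 0, config$ed_sd))

  k_hs <- 6L; k_bs <- 3L
  resp_id <- sprintf("R%05d", seq_len(n))

  alloc_items <- function(pool, k, energy_tot) {
    # k items per respondent from pool, energy split by normalized Exp(1).
    idx <- matrix(sample(pool, n * k, replace = TRUE), nrow = n)
    wts <- matrix(rexp(n * k), nrow = n)
    wts <- wts / rowSums(wts)
    list(food_id = as.vector(idx), energy = as.vector(wts * energy_tot),
         respondent = rep(resp_id, times = k))
  }

  e_healthy <- e_target * (1 - p_target)
  e_bad <- e_target * p_target
  hs <- alloc_items(healthy_solid, k_hs, e_healthy * 0.85)
  hb <- alloc_items(healthy_bev, 1L, e_healthy * 0.15)
  bs <- alloc_items(bad_solid, k_bs, e_bad * 0.65)
  bb <- alloc_items(bad_bev, 1L, e_bad * 0.25)
  lb <- alloc_items(low_bev, 1L, e_bad * 0.10)

  items <- tibble(
    respondent_id = c(hs$respondent, hb$respondent, bs$respondent,
                      bb$respondent, lb$respondent),
    food_id = c(hs$food_id, hb$food_id, bs$food_id, bb$food_id, lb$food_id),
    energy = c(hs$energy, hb$energy, bs$energy, bb$energy, lb$energy)
  )
  items$amount_g <- items$energy / epg[items$food_id]
  items$is_bev <- foods$is_beverage[match(items$food_id, foods$food_id)]

  # Fiber top-up: add the fiber-carrier vegetable to reach the planted
  # fiber-density target (clipped at zero when the recall already exceeds it).
  per_resp <- items %>%
    group_by(.data$respondent_id) %>%
    summarise(fiber_cur = sum(.data$amount_g * fpg[.data$food_id]),
              energy_cur = sum(.data$energy),
              solid_energy = sum(.data$energy[!.data$is_bev]),
              solid_grams = sum(.data$amount_g[!.data$is_bev]),
              .groups = "drop")
  stopifnot(identical(per_resp$respondent_id, resp_id))
  fib_need <- pmax(0, f_target * e_target / 1000 - per_resp$fiber_cur)
  fib_g <- fib_need / fpg[FIBER_FOOD_ID]
  fib_e <- fib_g * epg[FIBER_FOOD_ID]

  # Energy-density dilution: add the water-rich vegetable until the
  # energy density over non-beverage items drops to its target (the pools
  # are denser than any target by construction, so dilution is one-sided).
  se <- per_resp$solid_energy + fib_e
  sg <- per_resp$solid_grams + fib_g
  dw <- epg[WATER_FOOD_ID]
  dil_g <- pmax(0, (se - d_target * sg) / (d_target - dw))
  dil_e <- dil_g * dw

  extra <- tibble(
    respondent_id = rep(resp_id, 2),
    food_id = rep(c(FIBER_FOOD_ID, WATER_FOOD_ID), each = n),
    amount_g = c(fib_g, dil_g)
  )
  extra <- extra[extra$amount_g > 0, ]
  recalls <- bind_rows(items[, c("respondent_id", "food_id", "amount_g")],
                       extra) %>%
    arrange(.data$respondent_id, .data$food_id)

  # Exact ties in the compliance measure: a block of respondents shares one
  # recall verbatim.
  if (config$tie_fraction > 0) {
    m <- floor(config$tie_fraction * n)
    if (m >= 2) {
      tied <- resp_id[seq_len(m)]
      template <- recalls[recalls$respondent_id == tied[1], ]
      recalls <- recalls[!recalls$respondent_id %in% tied[-1], ]
      dup <- template[rep(seq_len(nrow(template)), m - 1), ]
      dup$respondent_id <- rep(tied[-1], each = nrow(template))
      recalls <- arrange(bind_rows(recalls, dup),
                         .data$respondent_id, .data$food_id)
    }
  }

  e_real <- recalls %>%
    group_by(.data$respondent_id) %>%
    summarise(ei = sum(.data$amount_g * epg[.data$food_id]), .groups = "drop")
  stopifnot(identical(e_real$respondent_id, resp_id))
  ei <- e_real$ei

  # Misreporting mixture: draw status and target EI/EER ratio, then
  # back-solve height (at a sampled BMI) so the implied EER gives the drawn
  # ratio exactly.
  status <- sample(c("UNDER", "PLAUSIBLE", "OVER"), n, replace = TRUE,
                   prob = config$misreporting_mixture)
  rr <- config$ratio_ranges
  ratio <- numeric(n)
  for (st in c("UNDER", "PLAUSIBLE", "OVER")) {
    i <- status == st
    rng <- rr[[tolower(st)]]
    ratio[i] <- runif(sum(i), rng[1], rng[2])
  }
  eer_target <- ei / ratio

  sex <- sample(c("M", "F"), n, replace = TRUE)
  age <- round(runif(n, 19, 85))
  pal <- sample(PAL_CATEGORIES, n, replace = TRUE,
                prob = c(0.45, 0.25, 0.2, 0.1))
  bmi <- pmin(45, pmax(18, rnorm(n, 27.5, 4.5)))
  pa_tab <- iom_pa_coefficients()
  pa <- ifelse(sex == "M", pa_tab$M[pal], pa_tab$F[pal])
  icpt <- ifelse(sex == "M", 662, 354)
  b_age <- ifelse(sex == "M", 9.53, 6.91)
  w_coef <- ifelse(sex == "M", 15.91, 9.36)
  h_coef <- ifelse(sex == "M", 539.6, 726)
  lhs <- eer_target - icpt + b_age * age
  if (any(lhs <= 0)) abort("EER target infeasible for sampled demographics.")
  a2 <- pa * w_coef * bmi
  a1 <- pa * h_coef
  height <- (-a1 + sqrt(a1^2 + 4 * a2 * lhs)) / (2 * a2)
  weight <- bmi * height^2

  survey_weight <- rlnorm(n, 0, 0.3)
  R <- config$replicate_count
  counts <- rmultinom(R, n, rep(1 / n, n))  # n x R resampling counts
  repw <- survey_weight * counts
  colnames(repw) <- paste0("repw_", seq_len(R))

  respondents <- tibble(
    respondent_id = resp_id,
    age_y = age, sex = sex, height_m = height, weight_kg = weight,
    pal_category = pal,
    smoking = sample(c("daily", "occasional", "never"), n, replace = TRUE,
                     prob = c(0.2, 0.1, 0.7)),
    bmi = bmi,
    survey_weight = survey_weight
  )
  respondents <- bind_cols(respondents, as_tibble(repw))

  truth <- tibble(
    respondent_id = resp_id,
    latent_score = u,
    target_pct_energy_tier4_other = 100 * p_target,
    target_energy_kcal = e_target,
    target_fiber_g_per_1000kcal = f_target,
    target_energy_density = d_target,
    intended_status = status,
    intended_ratio = ratio
  )
  attr(truth, "planted_effects") <- config$planted_effects

  list(respondents = respondents, recalls = recalls, truth = truth)
}

#' Extract the replicate-weight matrix from a respondent table
#'
#' @param respondents respondent tibble with `repw_*` columns.
#' @return Numeric matrix, one column per replicate.
#' @export
replicate_weight_matrix <- function(respondents) {
  cols <- grep("^repw_", names(respondents), value = TRUE)
  if (length(cols) < 2) abort("Respondent table has fewer than 2 repw_ columns.")
  as.matrix(respondents[, cols])
}

#' Generate and write a complete synthetic study directory
#'
#' Writes `foods.csv`, `recalls.csv`, `respondents.csv`, `gi_table.csv` and
#' `truth.json` in the CSV dialects read back by [read_study()].
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the list of generated objects.
#' @export
simulate_study <- function(config = simulation_config(), dir) {
  fooddb <- simulate_food_database(config)
  pop <- simulate_population(config, fooddb)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(fooddb$foods, file.path(dir, "foods.csv"))
  readr::write_csv(pop$recalls, file.path(dir, "recalls.csv"))
  readr::write_csv(pop$respondents, file.path(dir, "respondents.csv"))
  gi <- tibble(subgroup = names(fooddb$gi_table), gi = unname(fooddb$gi_table))
  fb <- tibble(subgroup = paste0("fallback:", names(fooddb$gi_fallback)),
               gi = unname(fooddb$gi_fallback))
  readr::write_csv(bind_rows(gi, fb), file.path(dir, "gi_table.csv"))
  jsonlite::write_json(
    list(config = unclass(config),
         planted_effects = config$planted_effects,
         truth = pop$truth),
    file.path(dir, "truth.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA
  )
  invisible(list(fooddb = fooddb, respondents = pop$respondents,
                 recalls = pop$recalls, truth = pop$truth))
}
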