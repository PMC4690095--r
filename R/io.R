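# Readers, validation, study configuration and the end-to-end pipeline.

#' Default study configuration
#'
#' Bundles the analysis settings: HCST thresholds, IOM PA coefficients, the
#' EWCFG recommended daily servings by DRI age-sex group, the DRI age bins
#' (19-30, 31-50, 51-70, >70 by sex), the significance level (0.001),
#' whether quartiles are survey-weighted, and the BRR variance scale factor.
#' Any entry can be overridden via a YAML file ([read_study_config()]) or by
#' editing the returned list.
#'
#' @return A named list of class `study_config`.
#' @export
default_study_config <- function() {
  rec <- tibble(
    major_group = rep(EWCFG_GROUPS, each = 8),
    sex = rep(rep(c("M", "F"), 4), 4),
    age_group = rep(rep(c("19-30", "31-50", "51-70", ">70"), each = 2), 4),
    rec_min = c(8, 7, 8, 7, 7, 7, 7, 7,      # Vegetables & Fruit
                8, 6, 8, 6, 7, 6, 7, 6,      # Grain Products
                2, 2, 2, 2, 3, 3, 3, 3,      # Milk & Alternatives
                3, 2, 3, 2, 3, 2, 3, 2),     # Meat & Alternatives
    rec_max = c(10, 8, 10, 8, 7, 7, 7, 7,
                8, 7, 8, 7, 7, 6, 7, 6,
                2, 2, 2, 2, 3, 3, 3, 3,
                3, 2, 3, 2, 3, 2, 3, 2)
  )
  structure(list(
    thresholds = hcst_thresholds(),
    pa_table = iom_pa_coefficients(),
    recommended_servings = rec,
    dri_age_breaks = c(19, 31, 51, 71, Inf),
    dri_age_labels = c("19-30", "31-50", "51-70", ">70"),
    alpha = 0.001,
    weighted_quartiles = TRUE,
    brr_scale = 1
  ), class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Reads overrides from a YAML file and merges them over
#' [default_study_config()]. Threshold entries are passed to
#' [hcst_thresholds()]; the PA table replaces the default wholesale when
#' present.
#'
#' @param path YAML file path.
#' @return A `study_config` list.
#' @export
read_study_config <- function(path) {
  cfg <- default_study_config()
  ov <- yaml::read_yaml(path)
  if (!is.null(ov$thresholds)) {
    cfg$thresholds <- do.call(hcst_thresholds, ov$thresholds)
  }
  if (!is.null(ov$pa_table)) {
    cfg$pa_table <- lapply(ov$pa_table, function(x) unlist(x))
  }
  for (k in c("alpha", "weighted_quartiles", "brr_scale")) {
    if (!is.null(ov[[k]])) cfg[[k]] <- ov[[k]]
  }
  cfg
}

#' DRI age-sex group labels
#'
#' @param age_y ages in years.
#' @param sex `"M"`/`"F"`.
#' @param config study configuration (for the age bins).
#' @return Character vector like `"M 19-30"`.
#' @export
dri_group <- function(age_y, sex, config = default_study_config()) {
  bin <- cut(age_y, breaks = config$dri_age_breaks,
             labels = config$dri_age_labels, right = FALSE)
  paste(sex, as.character(bin))
}

#' Read a study directory
#'
#' Loads and validates `foods.csv`, `recalls.csv` and `respondents.csv`
#' (plus `gi_table.csv` and `truth.json` when present). Schema mismatches
#' raise an error naming the offending columns; recall rows referencing
#' unknown foods raise an error with row numbers. Exclusions mirroring the
#' survey protocol are applied and logged: respondents aged under 19 are
#' removed entirely; respondents missing height, weight or activity remain
#' in the descriptive tables but are flagged out of the compliance analysis
#' (`in_compliance_sample`).
#'
#' @param dir study directory as written by [simulate_study()].
#' @return List: `foods`, `recalls`, `respondents`, `gi_table`,
#'   `gi_fallback`, `truth` (or `NULL`), `exclusions` (named counts).
#' @export
read_study <- function(dir) {
  paths <- file.path(dir, c("foods.csv", "recalls.csv", "respondents.csv"))
  for (p in paths) if (!file.exists(p)) abort(paste0("Missing input file: ", p))
  foods <- readr::read_csv(paths[1], show_col_types = FALSE, progress = FALSE)
  recalls <- readr::read_csv(paths[2], show_col_types = FALSE, progress = FALSE)
  respondents <- readr::read_csv(paths[3], show_col_types = FALSE,
                                 progress = FALSE)

  check_schema <- function(tab, required, name) {
    missing_cols <- setdiff(required, names(tab))
    if (length(missing_cols)) {
      abort(sprintf("%s is missing column(s): %s", name,
                    paste(missing_cols, collapse = ", ")))
    }
  }
  check_schema(foods, FOOD_REQUIRED_COLS, "foods.csv")
  check_schema(recalls, RECALL_REQUIRED_COLS, "recalls.csv")
  check_schema(respondents, RESPONDENT_REQUIRED_COLS, "respondents.csv")
  validate_foods(foods)

  bad <- which(!recalls$food_id %in% foods$food_id)
  if (length(bad)) {
    abort(sprintf("recalls.csv references unknown food_id at row(s) %s%s.",
                  paste(head(bad, 10), collapse = ", "),
                  if (length(bad) > 10) ", ..." else ""))
  }
  orphan <- which(!recalls$respondent_id %in% respondents$respondent_id)
  if (length(orphan)) {
    abort(sprintf("recalls.csv references unknown respondent_id at row(s) %s.",
                  paste(head(orphan, 10), collapse = ", ")))
  }
  if (any(respondents$survey_weight <= 0)) abort("survey_weight must be > 0.")
  repw_cols <- grep("^repw_", names(respondents), value = TRUE)
  if (length(repw_cols) &&
      any(as.matrix(respondents[, repw_cols]) < 0, na.rm = TRUE)) {
    abort("Replicate weights must be >= 0.")
  }
  bmi_chk <- respondents$weight_kg / respondents$height_m^2
  bad_bmi <- which(is.finite(bmi_chk) & is.finite(respondents$bmi) &
                     abs(bmi_chk - respondents$bmi) > 1e-6 * pmax(1, bmi_chk))
  if (length(bad_bmi)) {
    warn(sprintf("%d respondent(s) have bmi inconsistent with weight/height^2.",
                 length(bad_bmi)))
  }

  n0 <- nrow(respondents)
  underage <- !is.na(respondents$age_y) & respondents$age_y < 19
  if (any(underage)) {
    inform(sprintf("Excluded %d respondent(s) aged <19 years.", sum(underage)))
    respondents <- respondents[!underage, ]
    recalls <- recalls[recalls$respondent_id %in% respondents$respondent_id, ]
  }
  incomplete <- is.na(respondents$height_m) | is.na(respondents$weight_kg) |
    is.na(respondents$pal_category) |
    !respondents$respondent_id %in% recalls$respondent_id
  respondents$in_compliance_sample <- !incomplete
  if (any(incomplete)) {
    inform(sprintf(
      "%d respondent(s) lack height/weight/activity/intake; excluded from the compliance analysis.",
      sum(incomplete)))
  }

  gi_path <- file.path(dir, "gi_table.csv")
  gi_table <- NULL; gi_fallback <- NULL
  if (file.exists(gi_path)) {
    gt <- readr::read_csv(gi_path, show_col_types = FALSE, progress = FALSE)
    fb <- grepl("^fallback:", gt$subgroup)
    gi_table <- setNames(gt$gi[!fb], gt$subgroup[!fb])
    gi_fallback <- setNames(gt$gi[fb], sub("^fallback:", "", gt$subgroup[fb]))
  }
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::fromJSON(truth_path)
  } else NULL

  list(foods = foods, recalls = recalls, respondents = respondents,
       gi_table = gi_table, gi_fallback = gi_fallback, truth = truth,
       exclusions = c(underage = n0 - nrow(respondents),
                      incomplete = sum(incomplete)))
}

#' Run the full HCST analysis pipeline
#'
#' Classify foods, summarise recalls, classify misreporting, assign
#' compliance quartiles and compare outcomes across quartiles. Produces the
#' five report tables: per-food classification; per-respondent diet
#' summaries; the servings report (weighted mean Food Guide servings/day by
#' DRI age-sex group, both Tiers 1-3 and Tiers 1-4, next to the EWCFG
#' recommendation); the energy report (weighted mean kcal/day from Tiers
#' 1-3 combined, Tier 4 and each "other" category, by DRI group); and the
#' compliance report (quartile-wise weighted means with BRR standard errors
#' and trend tests, adjusted for age, sex and reporter status).
#'
#' @param study list from [read_study()] (or [simulate_study()]'s invisible
#'   return reshaped the same way).
#' @param config a `study_config` list.
#' @param out_dir optional directory; when given, every report is written as
#'   a CSV along with a `run_log.txt` containing the configuration hash and
#'   exclusion counts.
#' @return List of tibbles: `classification`, `summaries`, `reporters`,
#'   `servings_report`, `energy_report`, `compliance_report` (with quartile
#'   cut points as attribute `"cutpoints"`).
#' @export
run_pipeline <- function(study, config = default_study_config(),
                         out_dir = NULL) {
  foods <- study$foods
  classification <- classify_foods(foods, config$thresholds)
  summaries <- summarize_recalls(study$recalls, foods, classification)

  respondents <- study$respondents
  if (is.null(respondents$in_compliance_sample)) {
    respondents$in_compliance_sample <- TRUE
  }
  joined <- respondents %>%
    inner_join(summaries, by = "respondent_id")
  rep_stat <- classify_reporters(joined, joined$total_energy_kcal,
                                 config$pa_table)
  joined <- joined %>%
    left_join(rep_stat, by = "respondent_id") %>%
    mutate(dri_group = dri_group(.data$age_y, .data$sex, config))

  servings_report <- build_servings_report(joined, config)
  energy_report <- build_energy_report(joined, config)

  comp <- joined[joined$in_compliance_sample, , drop = FALSE]
  repw <- replicate_weight_matrix(respondents)[
    match(comp$respondent_id, respondents$respondent_id), , drop = FALSE]
  outcomes <- c(
    "age_y", "bmi", "total_energy_kcal",
    "pct_energy_fat", "pct_energy_satfat", "pct_energy_carb",
    "pct_energy_added_sugar", "pct_energy_protein", "pct_energy_alcohol",
    "fiber_g_per_1000kcal", "sodium_mg_per_1000kcal",
    "calcium_mg_per_1000kcal", "iron_mg_per_1000kcal",
    "vitc_mg_per_1000kcal", "mean_gi", "glycemic_load",
    "energy_density_kcal_per_g"
  )
  comp$female <- comp$sex == "F"
  comp$under_reporter <- comp$reporter_status == "UNDER"
  comp$over_reporter <- comp$reporter_status == "OVER"
  outcomes <- c(outcomes, "female", "under_reporter", "over_reporter")
  compliance_report <- compare_groups(
    comp, outcomes, repw,
    covariates = c("age_y", "sex", "reporter_status"),
    weighted = config$weighted_quartiles, alpha = config$alpha,
    scale = config$brr_scale
  )

  res <- list(classification = classification, summaries = summaries,
              reporters = rep_stat, servings_report = servings_report,
              energy_report = energy_report,
              compliance_report = compliance_report)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (nm in names(res)) {
      readr::write_csv(res[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
    log_lines <- c(
      paste0("config_hash: ", rlang::hash(config)),
      paste0("n_respondents: ", nrow(respondents)),
      paste0("n_compliance_sample: ", nrow(comp)),
      paste0("exclusions: ", paste(names(study$exclusions),
                                   study$exclusions, sep = "=",
                                   collapse = ", ")),
      paste0("quartile_cutpoints: ",
             paste(round(attr(compliance_report, "cutpoints"), 4),
                   collapse = ", "))
    )
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  res
}

# Weighted mean servings/day by DRI group, Tiers 1-3 and Tiers 1-4, with the
# EWCFG recommendation attached.
build_servings_report <- function(joined, config) {
  rows <- list()
  repw_all <- NULL
  for (g in EWCFG_GROUPS) {
    t13 <- rowSums(joined[, paste0("servings_", g, "_T", 1:3)])
    t14 <- t13 + joined[[paste0("servings_", g, "_T4")]]
    for (rng in c("Tiers 1-3", "Tiers 1-4")) {
      v <- if (rng == "Tiers 1-3") t13 else t14
      agg <- joined %>%
        mutate(v = v) %>%
        group_by(.data$dri_group) %>%
        summarise(mean = weighted_mean(.data$v, .data$survey_weight),
                  n = dplyr::n(), .groups = "drop")
      agg$major_group <- g
      agg$tier_range <- rng
      rows[[length(rows) + 1]] <- agg
    }
  }
  out <- bind_rows(rows)
  out$sex <- substr(out$dri_group, 1, 1)
  out$age_group <- sub("^[MF] ", "", out$dri_group)
  out %>%
    left_join(config$recommended_servings,
              by = c("major_group", "sex", "age_group")) %>%
    select("major_group", "tier_range", "dri_group", "mean", "n",
           "rec_min", "rec_max")
}

# Weighted mean kcal/day by DRI group for Tiers 1-3 combined, Tier 4 and
# each "other" category, plus the combined Tier 4 + other total and its
# percentage of energy.
build_energy_report <- function(joined, config) {
  cat_cols <- c("energy_TIER1", "energy_TIER2", "energy_TIER3",
                "energy_TIER4", paste0("energy_", OTHER_CATEGORIES))
  long <- joined %>%
    mutate(energy_TIERS123 = .data$energy_TIER1 + .data$energy_TIER2 +
             .data$energy_TIER3,
           energy_tier4_other = .data$energy_TIER4 + .data$energy_other) %>%
    tidyr::pivot_longer(all_of(c("energy_TIERS123", "energy_TIER4",
                                 paste0("energy_", OTHER_CATEGORIES),
                                 "energy_tier4_other", "total_energy_kcal")),
                        names_to = "category", values_to = "kcal") %>%
    group_by(.data$dri_group, .data$category) %>%
    summarise(mean_kcal = weighted_mean(.data$kcal, .data$survey_weight),
              .groups = "drop")
  pct <- joined %>%
    group_by(.data$dri_group) %>%
    summarise(mean_kcal = weighted_mean(.data$pct_energy_tier4_other,
                                        .data$survey_weight),
              .groups = "drop") %>%
    mutate(category = "pct_energy_tier4_other")
  bind_rows(long, pct) %>% arrange(.data$dri_group, .data$category)
}
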