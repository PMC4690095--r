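# Energy-misreporting classification against IOM Estimated Energy Requirements.

#' Default IOM physical-activity coefficients for adults
#'
#' PA coefficients entering the adult IOM factorial EER equations, by sex and
#' physical-activity category. The table is configurable: pass a modified
#' copy to [compute_eer()].
#'
#' @return Named list with elements `M` and `F`, each a named numeric vector
#'   over `sedentary`, `low_active`, `active`, `very_active`.
#' @export
iom_pa_coefficients <- function() {
  list(
    M = c(sedentary = 1.00, low_active = 1.11, active = 1.25, very_active = 1.48),
    F = c(sedentary = 1.00, low_active = 1.12, active = 1.27, very_active = 1.45)
  )
}

#' Estimated Energy Requirement (adult IOM factorial equations)
#'
#' Men: `EER = 662 - 9.53 * age + PA * (15.91 * weight + 539.6 * height)`;
#' women: `EER = 354 - 6.91 * age + PA * (9.36 * weight + 726 * height)`,
#' with age in years, weight in kg, height in metres and the PA coefficient
#' looked up from (sex, activity category).
#'
#' @param age_y age in years (adults, >= 19).
#' @param sex `"M"` or `"F"`.
#' @param weight_kg body weight, kg.
#' @param height_m height, metres.
#' @param pal_category one of `"sedentary"`, `"low_active"`, `"active"`,
#'   `"very_active"`.
#' @param pa_table PA coefficient table, default [iom_pa_coefficients()].
#' @return EER in kcal/day.
#' @export
#' @examples
#' compute_eer(30, "M", 80, 1.80, "sedentary") # 2620.18
compute_eer <- function(age_y, sex, weight_kg, height_m, pal_category,
                        pa_table = iom_pa_coefficients()) {
  if (!all(sex %in% c("M", "F"))) abort("sex must be 'M' or 'F'.")
  if (!all(pal_category %in% PAL_CATEGORIES)) {
    abort(paste0("Unknown pal_category value(s): ",
                 paste(unique(pal_category[!pal_category %in% PAL_CATEGORIES]),
                       collapse = ", ")))
  }
  stopifnot(all(weight_kg > 0), all(height_m > 0), all(age_y >= 19))
  pa <- ifelse(sex == "M", pa_table$M[pal_category], pa_table$F[pal_category])
  ifelse(sex == "M",
         662 - 9.53 * age_y + pa * (15.91 * weight_kg + 539.6 * height_m),
         354 - 6.91 * age_y + pa * (9.36 * weight_kg + 726 * height_m))
}

#' Reporter status from the EI/EER ratio
#'
#' Respondents whose reported energy intake (EI) is less than 70% of their
#' EER are under-reporters; more than 142% are over-reporters; those between
#' 70% and 142% inclusive are plausible reporters.
#'
#' @param ei reported energy intake, kcal/day (>= 0).
#' @param eer estimated energy requirement, kcal/day (> 0).
#' @return Character vector: `"UNDER"`, `"PLAUSIBLE"` or `"OVER"`.
#' @export
#' @examples
#' reporter_status(c(1399, 1400, 2841), c(2000, 2000, 2000))
reporter_status <- function(ei, eer) {
  if (any(eer <= 0)) abort("EER must be > 0.")
  if (any(ei < 0)) abort("Energy intake must be >= 0.")
  ratio <- ei / eer
  ifelse(ratio < 0.70, "UNDER", ifelse(ratio > 1.42, "OVER", "PLAUSIBLE"))
}

#' Classify respondents' energy misreporting
#'
#' Convenience wrapper combining [compute_eer()] and [reporter_status()] for
#' a respondent table joined to reported energy intakes.
#'
#' @param respondents respondent table (`age_y`, `sex`, `weight_kg`,
#'   `height_m`, `pal_category`).
#' @param ei reported energy intake per respondent, kcal/day.
#' @param pa_table PA coefficient table.
#' @return Tibble: `respondent_id`, `eer_kcal`, `ei_eer_ratio`,
#'   `reporter_status`.
#' @export
classify_reporters <- function(respondents, ei,
                               pa_table = iom_pa_coefficients()) {
  eer <- compute_eer(respondents$age_y, respondents$sex,
                     respondents$weight_kg, respondents$height_m,
                     respondents$pal_category, pa_table)
  tibble(
    respondent_id = respondents$respondent_id,
    eer_kcal = eer,
    ei_eer_ratio = ei / eer,
    reporter_status = reporter_status(ei, eer)
  )
}
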