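# Compliance quartiles and survey-weighted comparison across quartiles.

#' Survey-weighted mean
#'
#' @param values numeric vector.
#' @param weights positive weights, same length.
#' @return `sum(w * x) / sum(w)`.
#' @export
weighted_mean <- function(values, weights = rep(1, length(values))) {
  if (length(values) == 0) abort("weighted_mean() of an empty vector.")
  if (length(weights) != length(values)) abort("values and weights differ in length.")
  if (sum(weights) <= 0) abort("Sum of weights must be > 0.")
  sum(weights * values) / sum(weights)
}

#' Weighted quartile cut points (inverse weighted empirical CDF)
#'
#' The p-quantile is the smallest observed value whose cumulative normalized
#' weight reaches p. With equal weights this reproduces the usual
#' order-statistic quartiles.
#'
#' @param x numeric values.
#' @param weights positive weights.
#' @param probs probabilities (default the three quartile boundaries).
#' @return Numeric vector of cut points.
#' @export
weighted_quartile_cuts <- function(x, weights = rep(1, length(x)),
                                   probs = c(0.25, 0.5, 0.75)) {
  stopifnot(length(x) == length(weights), all(weights > 0))
  ord <- order(x)
  cw <- cumsum(weights[ord]) / sum(weights)
  vapply(probs, function(p) x[ord][which(cw >= p - 1e-12)[1]], numeric(1))
}

#' Assign HCST compliance quartiles
#'
#' Respondents are ranked by the percentage of their energy intake from
#' Tier 4 plus "other" foods/beverages and split at the (optionally
#' survey-weighted) quartile boundaries. Values exactly on a boundary fall
#' into the lower quartile. Quartile 1 ("compliers") has the lowest
#' percentage of energy from non-recommended foods; quartile 4 are
#' "non-compliers"; quartiles 2-3 are "intermediates".
#'
#' @param pct_values percentage-of-energy values (one per respondent).
#' @param weights survey weights; `NULL` for unweighted quartiles.
#' @return A list: `quartile` (integer 1-4 per respondent), `label`
#'   (`"COMPLIER"`, `"INTERMEDIATE"`, `"NON_COMPLIER"`), `cutpoints`
#'   (the three boundaries).
#' @export
assign_quartiles <- function(pct_values, weights = NULL) {
  n <- length(pct_values)
  if (n < 4) abort("At least 4 respondents are required to form quartiles.")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights <= 0)) abort("Survey weights must be > 0.")
  cuts <- weighted_quartile_cuts(pct_values, weights)
  q <- 1L + (pct_values > cuts[1]) + (pct_values > cuts[2]) +
    (pct_values > cuts[3])
  if (length(unique(pct_values)) == 1) {
    warn("All compliance values identical: degenerate quartiles (everyone in Q1).")
  }
  label <- c("COMPLIER", "INTERMEDIATE", "INTERMEDIATE", "NON_COMPLIER")[q]
  list(quartile = as.integer(q), label = label, cutpoints = cuts)
}

#' Bootstrap replicate-weight (BRR) standard error
#'
#' Recomputes a weighted statistic under each replicate weight vector and
#' returns `sqrt(scale * mean((theta_r - theta_hat)^2))`, the standard
#' bootstrap balanced-repeated-replication variance estimate used for
#' complex-survey designs.
#'
#' @param values numeric outcome vector.
#' @param weights main survey weights.
#' @param replicate_weights matrix, `length(values)` rows by R >= 2 replicate
#'   columns, entries >= 0.
#' @param statistic function `(values, weights) -> scalar`; defaults to the
#'   weighted mean.
#' @param scale variance scale factor (default 1).
#' @return Standard error (scalar).
#' @export
brr_se <- function(values, weights, replicate_weights,
                   statistic = weighted_mean, scale = 1) {
  replicate_weights <- as.matrix(replicate_weights)
  if (nrow(replicate_weights) != length(values)) {
    abort("replicate_weights must have one row per observation.")
  }
  if (ncol(replicate_weights) < 2) abort("At least 2 replicate weight sets required.")
  theta <- statistic(values, weights)
  theta_r <- apply(replicate_weights, 2, function(w) statistic(values, w))
  sqrt(scale * mean((theta_r - theta)^2))
}

# Weighted regression slope on the quartile score (internal work-horse).
# X: model matrix with the score in column 2. Returns the score coefficient.
fit_slope <- function(X, y, w, family) {
  keep <- w > 0
  if (family == "gaussian") {
    fit <- stats::lm.wfit(X[keep, , drop = FALSE], y[keep], w[keep])
    unname(fit$coefficients[2])
  } else {
    fit <- suppressWarnings(
      stats::glm.fit(X[keep, , drop = FALSE], y[keep], weights = w[keep],
                     family = stats::quasibinomial())
    )
    unname(fit$coefficients[2])
  }
}

#' Survey-weighted trend test across compliance quartiles
#'
#' Regresses the outcome on the quartile index treated as a linear score
#' (1-4), optionally adjusted for covariates, with survey weights.
#' Continuous outcomes use weighted least squares; binary outcomes a
#' weighted logistic model. The standard error of the score coefficient is
#' estimated by [brr_se()] over the replicate weights and the two-sided
#' p-value is taken from the normal reference distribution.
#'
#' @param outcome numeric (continuous) or logical/0-1 (binary) vector.
#' @param quartile integer quartile index 1-4 per respondent.
#' @param weights main survey weights.
#' @param replicate_weights replicate weight matrix (rows = respondents).
#' @param covariates optional data frame of adjustment covariates (e.g.,
#'   age, sex, reporter status); expanded via `model.matrix`.
#' @param family `"gaussian"` or `"binomial"`; guessed from the outcome if
#'   omitted.
#' @param alpha significance level reported alongside (default 0.001).
#' @param scale BRR variance scale factor.
#' @return Tibble with `slope`, `se`, `z`, `p_value`, `significant`.
#' @export
trend_test <- function(outcome, quartile, weights, replicate_weights,
                       covariates = NULL, family = NULL, alpha = 0.001,
                       scale = 1) {
  stopifnot(all(quartile %in% 1:4))
  if (is.logical(outcome)) outcome <- as.numeric(outcome)
  if (is.null(family)) {
    family <- if (all(outcome %in% c(0, 1))) "binomial" else "gaussian"
  }
  if (length(unique(outcome)) == 1) {
    warn("Constant outcome: trend is identically zero (p = 1).")
    return(tibble(slope = 0, se = NA_real_, z = 0, p_value = 1,
                  significant = FALSE))
  }
  X <- cbind(`(Intercept)` = 1, score = as.numeric(quartile))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    # constant covariates carry no information and break the factor contrasts
    keep_cov <- vapply(covariates, function(x) length(unique(x)) > 1,
                       logical(1))
    covariates <- covariates[, keep_cov, drop = FALSE]
    if (ncol(covariates)) {
      cov_mm <- stats::model.matrix(~ ., data = covariates)
      X <- cbind(X, cov_mm[, -1, drop = FALSE])
    }
  }
  replicate_weights <- as.matrix(replicate_weights)
  b <- fit_slope(X, outcome, weights, family)
  b_r <- apply(replicate_weights, 2, function(w) fit_slope(X, outcome, w, family))
  se <- sqrt(scale * mean((b_r - b)^2))
  z <- b / se
  p <- 2 * pnorm(-abs(z))
  tibble(slope = b, se = se, z = z, p_value = p, significant = p < alpha)
}

#' Compare outcomes across compliance quartiles
#'
#' Produces the compliance report: for each outcome, the survey-weighted
#' mean (or percentage, for binary outcomes) with BRR standard error in each
#' quartile, and the weighted trend test across quartiles adjusted for the
#' requested covariates. Quartiles are assigned from
#' `pct_energy_tier4_other` using [assign_quartiles()].
#'
#' @param data tibble with one row per respondent: diet summary joined to
#'   respondent covariates, `survey_weight` and `pct_energy_tier4_other`.
#' @param outcomes character vector of outcome column names (numeric or
#'   logical).
#' @param replicate_weights replicate weight matrix (rows aligned to
#'   `data`).
#' @param covariates character vector of covariate column names used to
#'   adjust the trend tests (default age, sex and reporter status).
#' @param weighted use survey-weighted quartile boundaries (default) or
#'   unweighted.
#' @param alpha significance level (default 0.001).
#' @param scale BRR variance scale factor.
#' @param pairwise also compute Bonferroni-corrected pairwise weighted
#'   contrasts between quartiles (returned as attribute `"pairwise"`).
#' @return A tibble (one row per outcome x quartile) with columns `outcome`,
#'   `quartile`, `group_label`, `mean`, `se`, `slope`, `p_trend`,
#'   `significant`; quartile cut points in attribute `"cutpoints"`.
#' @export
compare_groups <- function(data, outcomes, replicate_weights,
                           covariates = c("age_y", "sex", "reporter_status"),
                           weighted = TRUE, alpha = 0.001, scale = 1,
                           pairwise = FALSE) {
  drop <- rep(FALSE, nrow(data))
  for (cv in covariates) {
    if (!cv %in% names(data)) abort(sprintf("Missing covariate column '%s'.", cv))
    drop <- drop | is.na(data[[cv]])
  }
  drop <- drop | is.na(data$pct_energy_tier4_other) | is.na(data$survey_weight)
  if (any(drop)) {
    inform(sprintf("%d respondent(s) dropped for missing covariates.", sum(drop)))
    data <- data[!drop, , drop = FALSE]
    replicate_weights <- as.matrix(replicate_weights)[!drop, , drop = FALSE]
  }
  w <- data$survey_weight
  qa <- assign_quartiles(data$pct_energy_tier4_other,
                         weights = if (weighted) w else NULL)
  covs <- if (length(covariates)) data[, covariates, drop = FALSE] else NULL

  replicate_weights <- as.matrix(replicate_weights)
  rows <- lapply(outcomes, function(oc) {
    y_all <- data[[oc]]
    if (is.logical(y_all)) y_all <- as.numeric(y_all)
    ok <- !is.na(y_all)
    y <- y_all[ok]
    quart <- qa$quartile[ok]
    wt <- w[ok]
    repw_ok <- replicate_weights[ok, , drop = FALSE]
    covs_ok <- if (is.null(covs)) NULL else covs[ok, , drop = FALSE]
    binary <- all(y %in% c(0, 1))
    tt <- trend_test(y, quart, wt, repw_ok,
                     covariates = covs_ok, alpha = alpha, scale = scale)
    per_q <- lapply(1:4, function(q) {
      idx <- quart == q
      if (!any(idx)) {
        return(tibble(quartile = q, mean = NA_real_, se = NA_real_))
      }
      m <- weighted_mean(y[idx], wt[idx])
      se <- brr_se(y[idx], wt[idx], repw_ok[idx, , drop = FALSE],
                   scale = scale)
      tibble(quartile = q,
             mean = if (binary) 100 * m else m,
             se = if (binary) 100 * se else se)
    })
    out <- bind_rows(per_q)
    out$outcome <- oc
    out$group_label <- c("COMPLIER", "INTERMEDIATE", "INTERMEDIATE",
                         "NON_COMPLIER")[out$quartile]
    out$slope <- tt$slope
    out$p_trend <- tt$p_value
    out$significant <- tt$significant
    out
  })
  res <- bind_rows(rows)[, c("outcome", "quartile", "group_label", "mean",
                             "se", "slope", "p_trend", "significant")]
  attr(res, "cutpoints") <- qa$cutpoints
  if (pairwise) {
    attr(res, "pairwise") <- pairwise_contrasts(data, outcomes, qa$quartile,
                                                w, replicate_weights, scale)
  }
  res
}

# Pairwise weighted mean contrasts between quartiles with Bonferroni
# correction (in place of design-based Tukey, which is not defined without
# the original survey software's machinery).
pairwise_contrasts <- function(data, outcomes, quartile, w, repw, scale = 1) {
  repw <- as.matrix(repw)
  pairs <- utils::combn(1:4, 2)
  rows <- list()
  for (oc in outcomes) {
    y <- data[[oc]]
    if (is.logical(y)) y <- as.numeric(y)
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      ia <- quartile == a; ib <- quartile == b
      diff_stat <- function(idx_a, idx_b, wt) {
        weighted_mean(y[idx_a], wt[idx_a]) - weighted_mean(y[idx_b], wt[idx_b])
      }
      d <- diff_stat(ia, ib, w)
      d_r <- apply(repw, 2, function(wr) diff_stat(ia, ib, wr))
      se <- sqrt(scale * mean((d_r - d)^2))
      p <- min(1, ncol(pairs) * 2 * pnorm(-abs(d / se)))
      rows[[length(rows) + 1]] <- tibble(outcome = oc, q_a = a, q_b = b,
                                         diff = d, se = se,
                                         p_bonferroni = p)
    }
  }
  bind_rows(rows)
}
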