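# Cohort descriptives: stratified prevalences, contingency tests, index means.

#' Pearson chi-square test of independence
#'
#' Pearson statistic without continuity correction for any r x c table of
#' counts; errors (rather than warning) when an expected cell is zero.
#'
#' @param table A matrix of non-negative integer counts, at least 2 x 2.
#' @return A tibble with `statistic`, `df`, `p.value`.
#' @examples
#' chisq_independence(matrix(c(252, 158, 183, 163), nrow = 2, byrow = TRUE))
#' @export
chisq_independence <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) {
    abort("chisq_independence(): table must be at least 2 x 2")
  }
  if (any(table < 0)) abort("chisq_independence(): counts must be >= 0")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0)) {
    abort("chisq_independence(): zero expected count; merge sparse categories")
  }
  fit <- suppressWarnings(chisq.test(table, correct = FALSE))
  tibble::tibble(statistic = unname(fit$statistic),
                 df = unname(fit$parameter),
                 p.value = fit$p.value)
}

#' Two-sample t-test for index means
#'
#' Student's pooled-variance test by default (the primary row of standard
#' statistical-software output); set `var_equal = FALSE` for Welch.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param var_equal Pool the variances (default `TRUE`).
#' @return A tibble with `statistic`, `df`, `p.value`, `mean_x`, `mean_y`.
#' @export
two_sample_ttest <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2) {
    abort("two_sample_ttest(): each group needs n >= 2")
  }
  fit <- t.test(x, y, var.equal = var_equal)
  tibble::tibble(statistic = unname(fit$statistic),
                 df = unname(fit$parameter),
                 p.value = fit$p.value,
                 mean_x = mean(x), mean_y = mean(y))
}

#' MSyn and component prevalence by stratum
#'
#' Counts and percentages of the MSyn diagnosis and each abnormal component,
#' for the total cohort and by sex.
#'
#' @param flags Output of [classify_atp3()].
#' @param strata Subset of `c("total", "male", "female")`.
#' @return A tibble: `stratum`, `measure`, `n_abnormal`, `n`, `pct`.
#' @export
prevalence_summary <- function(flags, strata = c("total", "male", "female")) {
  strata <- match.arg(strata, several.ok = TRUE)
  require_columns(flags, c("sex", "wc_abn", "fpg_abn", "bp_abn", "tg_abn",
                           "hdl_abn", "msyn"), "prevalence_summary")
  if (!nrow(flags)) abort("prevalence_summary(): empty cohort")
  measures <- c("wc_abn", "fpg_abn", "bp_abn", "tg_abn", "hdl_abn", "msyn")
  purrr::map_dfr(strata, function(st) {
    sub <- if (st == "total") flags else flags[flags$sex == st, ]
    if (!nrow(sub)) {
      warn(sprintf("prevalence_summary(): stratum '%s' is empty", st))
      return(tibble::tibble(stratum = st, measure = measures,
                            n_abnormal = 0L, n = 0L, pct = 0))
    }
    tibble::tibble(
      stratum = st,
      measure = measures,
      n_abnormal = vapply(measures, function(m) sum(sub[[m]]), integer(1),
                          USE.NAMES = FALSE),
      n = nrow(sub),
      pct = 100 * vapply(measures, function(m) mean(sub[[m]]), numeric(1),
                         USE.NAMES = FALSE)
    )
  })
}

#' WHO BMI category
#'
#' `< 18.5` underweight; `[18.5, 25)` normal; `[25, 30)` overweight; `>= 30`
#' obese (left-closed at 25 and 30).
#'
#' @param bmi BMI in kg/m^2 (vectorised, positive).
#' @return Factor with levels underweight/normal/overweight/obese.
#' @export
bmi_category <- function(bmi) {
  check_positive(bmi = bmi)
  cut(bmi, breaks = c(0, 18.5, 25, 30, Inf), right = FALSE,
      labels = c("underweight", "normal", "overweight", "obese"))
}

#' Index means by MSyn status and sex
#'
#' Mean and SD of each index per stratum and MSyn status, with the pooled
#' two-sample t-test contrasting MSyn-present vs MSyn-absent within stratum.
#'
#' @param indices Output of [compute_indices()].
#' @param flags Output of [classify_atp3()].
#' @param strata Subset of `c("total", "male", "female")`.
#' @return A tibble: `stratum`, `index`, `mean_msyn`, `sd_msyn`, `mean_no`,
#'   `sd_no`, `p.value`.
#' @export
index_summary <- function(indices, flags,
                          strata = c("total", "male", "female")) {
  strata <- match.arg(strata, several.ok = TRUE)
  merged <- dplyr::inner_join(indices, flags[, c("id", "msyn")], by = "id")
  cols <- c("wc", "whtr", "absi", "bri", "vai", "ci", "bmi")
  purrr::map_dfr(strata, function(st) {
    sub <- if (st == "total") merged else merged[merged$sex == st, ]
    purrr::map_dfr(cols, function(ix) {
      a <- sub[[ix]][sub$msyn]
      b <- sub[[ix]][!sub$msyn]
      p <- if (length(a) >= 2 && length(b) >= 2) {
        two_sample_ttest(a, b)$p.value
      } else NA_real_
      tibble::tibble(stratum = st, index = ix,
                     mean_msyn = mean(a), sd_msyn = sd(a),
                     mean_no = mean(b), sd_no = sd(b),
                     p.value = p)
    })
  })
}
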