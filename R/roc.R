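# ROC curves, AUC confidence intervals and Youden-optimal cutoffs.
#
# Positivity rule throughout: score > threshold predicts the positive class,
# so cutoffs are reported in the "greater than" style. Thresholds are the
# observed score values (no midpoint interpolation), plus a -Inf point so the
# curve always contains the (sens 1, spec 0) corner.

#' Build an empirical ROC curve
#'
#' One operating point per unique observed score plus the trivial extremes.
#' At threshold `c`, sensitivity is the proportion of cases with score `> c`
#' and specificity the proportion of controls with score `<= c`.
#'
#' @param scores Numeric marker values (finite).
#' @param labels Logical (or 0/1) outcome; `TRUE` = case.
#' @return A `msyn_roc` object: a tibble with columns `threshold`, `sens`,
#'   `spec`, and attributes `n_pos`, `n_neg`.
#' @examples
#' build_roc(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE))
#' @export
build_roc <- function(scores, labels) {
  labels <- validate_labels(scores, labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  thr <- c(-Inf, sort(unique(scores)))
  sens <- 1 - ecdf(pos)(thr)        # P(pos > c)
  spec <- ecdf(neg)(thr)            # P(neg <= c)
  curve <- tibble::tibble(threshold = thr, sens = sens, spec = spec)
  structure(curve, class = c("msyn_roc", class(curve)),
            n_pos = length(pos), n_neg = length(neg))
}

#' Trapezoidal area under the ROC curve
#'
#' Integrates sensitivity over 1 - specificity. With operating points at every
#' observed value this equals the Mann-Whitney estimate
#' `(#(pos > neg) + 0.5 * #(pos == neg)) / (n_pos * n_neg)`.
#'
#' @param curve A `msyn_roc` object from [build_roc()].
#' @return AUC as a proportion in `[0, 1]`.
#' @export
auc_trapezoid <- function(curve) {
  stopifnot(inherits(curve, "msyn_roc"))
  x <- 1 - curve$spec
  y <- curve$sens
  ord <- order(x, y)
  x <- x[ord]; y <- y[ord]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Confidence interval for the AUC
#'
#' Analytic methods give a Wald interval `auc +/- z * SE` clipped to `[0, 1]`:
#' `"hanley-mcneil"` uses the exponential-model variance approximation;
#' `"delong"` (default) the nonparametric placement-value variance. The
#' `"bootstrap"` method returns a stratified percentile interval.
#'
#' @param scores,labels As in [build_roc()].
#' @param method `"delong"`, `"hanley-mcneil"` or `"bootstrap"`.
#' @param level Confidence level (default 0.95).
#' @param reps Bootstrap replicates (default 2000).
#' @param seed Seed for the bootstrap (required for that method).
#' @return Named numeric `c(low, high)`.
#' @export
auc_ci <- function(scores, labels,
                   method = c("delong", "hanley-mcneil", "bootstrap"),
                   level = 0.95, reps = 2000, seed = NULL) {
  method <- match.arg(method)
  labels <- validate_labels(scores, labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  auc <- mann_whitney_auc(pos, neg)
  z <- qnorm(1 - (1 - level) / 2)

  if (method == "hanley-mcneil") {
    se <- hanley_mcneil_se(auc, length(pos), length(neg))
    ci <- auc + c(-1, 1) * z * se
  } else if (method == "delong") {
    se <- delong_se(pos, neg)
    ci <- auc + c(-1, 1) * z * se
  } else {
    if (is.null(seed)) abort("auc_ci(): bootstrap requires a seed")
    ci <- withr::with_seed(seed, {
      boot <- replicate(reps, {
        mann_whitney_auc(sample(pos, replace = TRUE),
                         sample(neg, replace = TRUE))
      })
      unname(quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2)))
    })
  }
  c(low = max(0, ci[1]), high = min(1, ci[2]))
}

#' Youden-optimal cutoff
#'
#' Maximises `J = sens + spec - 1` over the observed-value thresholds. Ties
#' are broken by higher sensitivity, then by the smaller threshold — a
#' screening context favours sensitivity.
#'
#' @param curve A `msyn_roc` object.
#' @return A tibble row with `cutoff`, `sens`, `spec`, `youden`.
#' @export
youden_optimal <- function(curve) {
  stopifnot(inherits(curve, "msyn_roc"))
  j <- curve$sens + curve$spec - 1
  best <- which(abs(j - max(j)) < 1e-12)
  best <- best[order(-curve$sens[best], curve$threshold[best])][1]
  tibble::tibble(
    cutoff = curve$threshold[best],
    sens = curve$sens[best],
    spec = curve$spec[best],
    youden = j[best]
  )
}

#' Discrimination band for an AUC
#'
#' `[0.9, 1]` excellent; `[0.8, 0.9)` good; `[0.7, 0.8)` fair; `[0.6, 0.7)`
#' poor; below 0.6, failed. Values below 0.5 are also "failed", with a
#' below-chance warning.
#'
#' @param auc AUC in `[0, 1]` (vectorised).
#' @return Character vector of band labels.
#' @export
discrimination_band <- function(auc) {
  if (any(!is.finite(auc)) || any(auc < 0) || any(auc > 1)) {
    abort("discrimination_band(): auc must be in [0, 1]")
  }
  if (any(auc < 0.5)) {
    warn("discrimination_band(): AUC below 0.5 (worse than chance)")
  }
  dplyr::case_when(
    auc >= 0.9 ~ "excellent",
    auc >= 0.8 ~ "good",
    auc >= 0.7 ~ "fair",
    auc >= 0.6 ~ "poor",
    TRUE ~ "failed"
  )
}

#' Evaluate one index as a screening marker
#'
#' Composes the ROC curve, AUC with confidence interval, Youden-optimal
#' cutoff with Wilson intervals for sensitivity and specificity, and the
#' discrimination band — one summary row of the screening table.
#'
#' @inheritParams auc_ci
#' @param ci_method Method passed to [auc_ci()].
#' @return A `msyn_roc_summary` object (the underlying `msyn_roc` curve is
#'   kept as an attribute for plotting).
#' @examples
#' set.seed(1)
#' evaluate_index(rnorm(100) + rep(0:1, 50), rep(c(FALSE, TRUE), 50))
#' @export
evaluate_index <- function(scores, labels, ci_method = "delong",
                           level = 0.95, reps = 2000, seed = NULL) {
  curve <- build_roc(scores, labels)
  auc <- auc_trapezoid(curve)
  ci <- auc_ci(scores, labels, method = ci_method, level = level,
               reps = reps, seed = seed)
  opt <- youden_optimal(curve)
  n_pos <- attr(curve, "n_pos")
  n_neg <- attr(curve, "n_neg")
  sens_ci <- wilson_interval(round(opt$sens * n_pos), n_pos, level)
  spec_ci <- wilson_interval(round(opt$spec * n_neg), n_neg, level)
  out <- list(
    auc = auc, ci_low = unname(ci[1]), ci_high = unname(ci[2]),
    cutoff = opt$cutoff, sens = opt$sens, spec = opt$spec,
    sens_low = sens_ci[1], sens_high = sens_ci[2],
    spec_low = spec_ci[1], spec_high = spec_ci[2],
    youden = opt$youden,
    band = discrimination_band(auc),
    n_pos = n_pos, n_neg = n_neg,
    ci_method = ci_method, level = level
  )
  structure(out, class = "msyn_roc_summary", curve = curve)
}

#' Screening table across strata and indices
#'
#' Builds one [evaluate_index()] row per index per stratum (total, male,
#' female), the shape of a full ROC summary table.
#'
#' @param indices Index table from [compute_indices()].
#' @param flags Classification table from [classify_atp3()].
#' @param index_cols Index columns to evaluate.
#' @param strata Subset of `c("total", "male", "female")`.
#' @inheritParams evaluate_index
#' @return A tibble with one row per stratum x index; strata whose labels are
#'   single-class are flagged `"not estimable"` in the `note` column.
#' @export
roc_table <- function(indices, flags,
                      index_cols = c("bmi", "wc", "bri", "absi", "vai", "ci", "whtr"),
                      strata = c("total", "male", "female"),
                      ci_method = "delong", level = 0.95,
                      reps = 2000, seed = NULL) {
  strata <- match.arg(strata, several.ok = TRUE)
  require_columns(flags, c("id", "msyn"), "roc_table")
  require_columns(indices, c("id", "sex", index_cols), "roc_table")
  merged <- dplyr::inner_join(indices, flags[, c("id", "msyn")], by = "id")

  purrr::map_dfr(strata, function(st) {
    sub <- if (st == "total") merged else merged[merged$sex == st, ]
    purrr::map_dfr(index_cols, function(ix) {
      base <- tibble::tibble(stratum = st, index = ix)
      if (length(unique(sub$msyn)) < 2) {
        return(dplyr::mutate(base, auc = NA_real_, ci_low = NA_real_,
                             ci_high = NA_real_, cutoff = NA_real_,
                             sens = NA_real_, spec = NA_real_,
                             youden = NA_real_, band = NA_character_,
                             note = "not estimable"))
      }
      fit <- evaluate_index(sub[[ix]], sub$msyn, ci_method = ci_method,
                            level = level, reps = reps, seed = seed)
      dplyr::bind_cols(base, tidy(fit)[, c("auc", "ci_low", "ci_high",
                                           "cutoff", "sens", "spec",
                                           "youden", "band")],
                       tibble::tibble(note = NA_character_))
    })
  })
}

# -- S3 methods ---------------------------------------------------------------

#' @export
print.msyn_roc_summary <- function(x, ...) {
  cat(sprintf(
    "ROC screening summary (n_pos = %d, n_neg = %d)\n  AUC %.3f (%d%% CI %.3f-%.3f, %s) [%s]\n  Youden-optimal cutoff > %.4g: sens %.1f%%, spec %.1f%%, J = %.4f\n",
    x$n_pos, x$n_neg, x$auc, round(100 * x$level), x$ci_low, x$ci_high,
    x$ci_method, x$band, x$cutoff, 100 * x$sens, 100 * x$spec, x$youden))
  invisible(x)
}

#' Tidy a ROC screening summary
#'
#' @param x A `msyn_roc_summary`.
#' @param ... Unused.
#' @return One-row tibble of the summary fields.
#' @exportS3Method generics::tidy
tidy.msyn_roc_summary <- function(x, ...) {
  tibble::as_tibble(x[c("auc", "ci_low", "ci_high", "cutoff", "sens", "spec",
                        "sens_low", "sens_high", "spec_low", "spec_high",
                        "youden", "band")])
}

#' Model-level summary of a ROC evaluation
#'
#' @inheritParams tidy.msyn_roc_summary
#' @return One-row tibble with sample sizes and the CI method.
#' @exportS3Method generics::glance
glance.msyn_roc_summary <- function(x, ...) {
  tibble::tibble(n_pos = x$n_pos, n_neg = x$n_neg,
                 ci_method = x$ci_method, level = x$level)
}

#' Plot a ROC curve
#'
#' @param object A `msyn_roc` or `msyn_roc_summary` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.msyn_roc <- function(object, ...) {
  df <- tibble::tibble(fpr = 1 - object$spec, tpr = object$sens)
  df <- df[order(df$fpr, df$tpr), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.msyn_roc
#' @exportS3Method ggplot2::autoplot
autoplot.msyn_roc_summary <- function(object, ...) {
  curve <- attr(object, "curve")
  autoplot(curve) +
    ggplot2::annotate("point", x = 1 - object$spec, y = object$sens,
                      colour = "red", size = 2) +
    ggplot2::labs(subtitle = sprintf("AUC %.3f (%s); cutoff > %.4g, J = %.3f",
                                     object$auc, object$band, object$cutoff,
                                     object$youden))
}

# -- internal -----------------------------------------------------------------

validate_labels <- function(scores, labels) {
  if (any(!is.finite(scores))) abort("scores must be finite")
  labels <- as.logical(labels)
  if (length(labels) != length(scores)) {
    abort("scores and labels must have equal length")
  }
  if (anyNA(labels)) abort("labels must not contain NA")
  if (length(unique(labels)) < 2) abort("degenerate labels: both classes required")
  labels
}

# Mann-Whitney AUC via midranks: exact with ties, O(n log n).
mann_whitney_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  n1 <- length(pos)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * length(neg))
}

hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

# DeLong placement-value SE for a single AUC.
delong_se <- function(pos, neg) {
  n1 <- length(pos)
  n0 <- length(neg)
  all_r <- rank(c(pos, neg))
  v10 <- (all_r[seq_len(n1)] - rank(pos)) / n0        # placements of cases
  v01 <- 1 - (all_r[n1 + seq_len(n0)] - rank(neg)) / n1
  sqrt(var(v10) / n1 + var(v01) / n0)
}

# Closed-form Wilson score interval for a binomial proportion.
wilson_interval <- function(x, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(max(0, centre - half), min(1, centre + half))
}
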