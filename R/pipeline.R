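# End-to-end cohort analysis: validated CSV input with an exclusion log,
# orchestration of indices -> classification -> descriptives -> ROC table,
# and report output as CSV/JSON with a run manifest.

#' Cohort CSV schema
#'
#' Column order of the pipeline's cohort CSV. Treatment flags are encoded
#' 0/1; `sex` is `"male"`/`"female"`. The four demographic columns are
#' free-form categoricals used only in descriptives.
#'
#' @return Character vector of column names.
#' @export
cohort_schema <- function() {
  c("id", "sex", "age", "height_cm", "weight_kg", "wc_cm",
    "sbp1", "sbp2", "dbp1", "dbp2",
    "fpg_mgdl", "tg_mgdl", "hdl_mgdl", "tc_mgdl",
    "treat_glucose", "treat_bp", "treat_tg", "treat_hdl",
    "smoking", "education", "income", "marital")
}

.mandatory_cols <- c("id", "sex", "height_cm", "weight_kg", "wc_cm",
                     "sbp1", "dbp1", "fpg_mgdl", "tg_mgdl", "hdl_mgdl")

#' Read and validate a cohort CSV
#'
#' Listwise validation: a missing mandatory column is fatal; rows failing
#' validation (missing or non-positive component inputs, unknown sex, waist
#' beyond the spherical bound) are excluded and logged, never silently
#' dropped. Unknown extra columns are accepted with a notice.
#'
#' @param path Path to a cohort CSV.
#' @return A validated tibble with an `exclusions` attribute (tibble of
#'   `row`, `id`, `reason`).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(sprintf("read_cohort(): no such file: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           id = readr::col_character(),
                           sex = readr::col_character(),
                           .default = readr::col_guess()))
  missing <- setdiff(.mandatory_cols, names(raw))
  if (length(missing)) {
    abort(sprintf("read_cohort(): missing mandatory column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(raw), cohort_schema())
  if (length(extra)) {
    inform(sprintf("read_cohort(): ignoring unknown column(s): %s",
                   paste(extra, collapse = ", ")))
  }
  for (tr in c("treat_glucose", "treat_bp", "treat_tg", "treat_hdl")) {
    raw[[tr]] <- if (tr %in% names(raw)) as.logical(raw[[tr]]) else FALSE
  }
  for (opt in c("sbp2", "dbp2")) {
    if (!opt %in% names(raw)) raw[[opt]] <- NA_real_
  }
  validate_cohort(raw)
}

validate_cohort <- function(raw) {
  reason <- rep(NA_character_, nrow(raw))
  flag <- function(bad, why) {
    bad <- which(bad & is.na(reason))
    reason[bad] <<- why
  }
  num_req <- c("height_cm", "weight_kg", "wc_cm", "sbp1", "dbp1",
               "fpg_mgdl", "tg_mgdl", "hdl_mgdl")
  for (col in num_req) {
    flag(is.na(raw[[col]]), paste("missing", sub("_.*", "", col)))
    flag(!is.na(raw[[col]]) & raw[[col]] <= 0, paste("non-positive", col))
  }
  flag(!raw$sex %in% c("male", "female"), "unknown sex")
  flag(!is.na(raw$wc_cm) & !is.na(raw$height_cm) &
         raw$wc_cm >= pi * raw$height_cm, "waist exceeds spherical bound")
  keep <- is.na(reason)
  exclusions <- tibble::tibble(row = which(!keep),
                               id = raw$id[!keep],
                               reason = reason[!keep])
  out <- raw[keep, intersect(cohort_schema(), names(raw))]
  structure(tibble::as_tibble(out), exclusions = exclusions)
}

#' Run the full screening analysis
#'
#' Indices, ATP III classification, component distribution, stratified
#' prevalence and index-mean tables, and the ROC screening table, in one
#' deterministic pass.
#'
#' @param cohort A cohort tibble ([read_cohort()], [generate_cohort()] or
#'   [fixture_cohort()]).
#' @param thresholds An [atp3_thresholds()] object.
#' @param ci_method AUC CI method (see [auc_ci()]).
#' @param strata Subset of `c("total", "male", "female")`.
#' @param seed Seed for any stochastic CI method (bootstrap).
#' @return A `msyn_report` list: `prevalence`, `components`, `index_means`,
#'   `roc`, `exclusions`, `config`.
#' @examples
#' rep <- run_analysis(fixture_cohort())
#' rep$roc
#' @export
run_analysis <- function(cohort, thresholds = atp3_thresholds(),
                         ci_method = "delong",
                         strata = c("total", "male", "female"),
                         seed = NULL) {
  strata <- match.arg(strata, several.ok = TRUE)
  indices <- compute_indices(cohort)
  flags <- classify_atp3(cohort, thresholds)
  report <- list(
    prevalence = prevalence_summary(flags, strata = strata),
    components = component_distribution(flags),
    index_means = index_summary(indices, flags, strata = strata),
    roc = roc_table(indices, flags, strata = strata,
                    ci_method = ci_method, seed = seed),
    exclusions = attr(cohort, "exclusions") %||%
      tibble::tibble(row = integer(), id = character(), reason = character()),
    config = list(thresholds = unclass(thresholds), ci_method = ci_method,
                  strata = strata, seed = seed,
                  n = nrow(cohort))
  )
  structure(report, class = "msyn_report")
}

#' Write a cohort report to disk
#'
#' One CSV per table, a JSON bundle, and a machine-readable run manifest
#' (config, seed, package and R versions).
#'
#' @param report A `msyn_report` from [run_analysis()].
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("csv", "json")`.
#' @return `dir`, invisibly.
#' @export
write_cohort_report <- function(report, dir, formats = c("csv", "json")) {
  stopifnot(inherits(report, "msyn_report"))
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c("prevalence", "components", "index_means", "roc", "exclusions")
  if ("csv" %in% formats) {
    for (tb in tables) {
      readr::write_csv(report[[tb]], file.path(dir, paste0(tb, ".csv")))
    }
  }
  if ("json" %in% formats) {
    jsonlite::write_json(report[tables], file.path(dir, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(
    config = report$config,
    package = as.character(utils::packageVersion("msynscreen")),
    r_version = R.version.string,
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.msyn_report <- function(x, ...) {
  msyn <- x$prevalence[x$prevalence$stratum == "total" &
                         x$prevalence$measure == "msyn", ]
  cat(sprintf("Metabolic-syndrome screening report (n = %d analysed, %d excluded)\n",
              x$config$n, nrow(x$exclusions)))
  if (nrow(msyn)) {
    cat(sprintf("  MSyn prevalence: %.1f%% (%d/%d)\n",
                msyn$pct, msyn$n_abnormal, msyn$n))
  }
  cat("  ROC screening table:\n")
  print(x$roc, n = Inf)
  invisible(x)
}

#' Tidy a cohort report
#'
#' @param x A `msyn_report`.
#' @param ... Unused.
#' @return The ROC screening table (one row per stratum x index).
#' @exportS3Method generics::tidy
tidy.msyn_report <- function(x, ...) x$roc

#' One-line summary of a cohort report
#'
#' @inheritParams tidy.msyn_report
#' @return One-row tibble: cohort size, exclusions, MSyn prevalence, best
#'   index by total-stratum AUC.
#' @exportS3Method generics::glance
glance.msyn_report <- function(x, ...) {
  msyn <- x$prevalence[x$prevalence$stratum == "total" &
                         x$prevalence$measure == "msyn", ]
  total_roc <- x$roc[x$roc$stratum == "total" & !is.na(x$roc$auc), ]
  best <- if (nrow(total_roc)) {
    total_roc$index[which.max(total_roc$auc)]
  } else NA_character_
  tibble::tibble(
    n = x$config$n,
    n_excluded = nrow(x$exclusions),
    msyn_prevalence = if (nrow(msyn)) msyn$pct / 100 else NA_real_,
    best_index = best,
    best_auc = if (nrow(total_roc)) max(total_roc$auc) else NA_real_
  )
}
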