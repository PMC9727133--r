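# NCEP ATP III metabolic-syndrome classification.
#
# Five components, each inclusive at its printed threshold; drug treatment for
# a component counts as abnormal regardless of the measured value. Diagnosis
# requires >= 3 abnormal components.

#' ATP III component thresholds
#'
#' Defaults follow the NCEP ATP III criteria: WC >= 102 cm (men) / 88 cm
#' (women); FPG >= 100 mg/dL; SBP >= 130 or DBP >= 85 mmHg; TG >= 150 mg/dL;
#' HDL-C <= 40 mg/dL (men) / 50 mg/dL (women). All comparisons are inclusive.
#'
#' @param wc_male,wc_female Waist cutoffs (cm, `>=`).
#' @param fpg Fasting plasma glucose cutoff (mg/dL, `>=`).
#' @param sbp,dbp Blood-pressure cutoffs (mmHg, `>=`).
#' @param tg Triglyceride cutoff (mg/dL, `>=`).
#' @param hdl_male,hdl_female HDL-C cutoffs (mg/dL, `<=`).
#' @return A named list of class `atp3_thresholds`.
#' @export
atp3_thresholds <- function(wc_male = 102, wc_female = 88, fpg = 100,
                            sbp = 130, dbp = 85, tg = 150,
                            hdl_male = 40, hdl_female = 50) {
  th <- list(wc_male = wc_male, wc_female = wc_female, fpg = fpg,
             sbp = sbp, dbp = dbp, tg = tg,
             hdl_male = hdl_male, hdl_female = hdl_female)
  if (any(vapply(th, function(x) !is.numeric(x) || length(x) != 1 || x <= 0,
                 logical(1)))) {
    abort("atp3_thresholds(): all thresholds must be single positive numbers")
  }
  structure(th, class = "atp3_thresholds")
}

#' Average two blood-pressure readings
#'
#' Per-channel arithmetic mean of two measurements; if the second reading is
#' missing the single reading is used and a warning is emitted.
#'
#' @param sbp1,sbp2 Systolic readings (mmHg).
#' @param dbp1,dbp2 Diastolic readings (mmHg).
#' @return A tibble with columns `sbp` and `dbp`.
#' @export
mean_bp <- function(sbp1, sbp2, dbp1, dbp2) {
  check_positive(sbp1 = sbp1, dbp1 = dbp1)
  if (any(is.na(sbp2)) || any(is.na(dbp2))) {
    warn("mean_bp(): missing second reading; using the single reading")
  }
  tibble::tibble(
    sbp = ifelse(is.na(sbp2), sbp1, (sbp1 + sbp2) / 2),
    dbp = ifelse(is.na(dbp2), dbp1, (dbp1 + dbp2) / 2)
  )
}

#' Classify ATP III components and metabolic syndrome
#'
#' Flags each of the five ATP III components per subject, counts them, and
#' diagnoses MSyn when three or more are abnormal. Blood pressure is the mean
#' of the two readings. Treatment flags (`treat_glucose`, `treat_bp`,
#' `treat_tg`, `treat_hdl`) force the corresponding component abnormal; if a
#' treatment column is absent it defaults to `FALSE` with a notice.
#'
#' Rows with a missing value in any component input are dropped with a
#' warning; use [read_cohort()] upstream for a full exclusion log.
#'
#' @param data Cohort table with columns `id`, `sex`, `wc_cm`, `fpg_mgdl`,
#'   `sbp1`, `sbp2`, `dbp1`, `dbp2`, `tg_mgdl`, `hdl_mgdl` and optional
#'   treatment flags.
#' @param thresholds An [atp3_thresholds()] object.
#' @return A tibble with columns `id`, `sex`, `wc_abn`, `fpg_abn`, `bp_abn`,
#'   `tg_abn`, `hdl_abn`, `count`, `msyn`.
#' @examples
#' classify_atp3(fixture_cohort())
#' @export
classify_atp3 <- function(data, thresholds = atp3_thresholds()) {
  stopifnot(inherits(thresholds, "atp3_thresholds"))
  require_columns(data, c("id", "sex", "wc_cm", "fpg_mgdl", "sbp1", "sbp2",
                          "dbp1", "dbp2", "tg_mgdl", "hdl_mgdl"),
                  "classify_atp3")
  for (tr in c("treat_glucose", "treat_bp", "treat_tg", "treat_hdl")) {
    if (!tr %in% names(data)) {
      inform(sprintf("classify_atp3(): column '%s' absent; assuming FALSE", tr))
      data[[tr]] <- FALSE
    }
  }
  sex <- check_sex(data$sex)

  required <- data[, c("wc_cm", "fpg_mgdl", "sbp1", "dbp1", "tg_mgdl",
                       "hdl_mgdl")]
  complete <- stats::complete.cases(required)
  if (any(!complete)) {
    warn(sprintf("classify_atp3(): dropping %d record(s) with missing component inputs: %s",
                 sum(!complete),
                 paste(head(data$id[!complete], 10), collapse = ", ")))
    data <- data[complete, ]
    sex <- sex[complete]
  }
  if (!nrow(data)) abort("classify_atp3(): no complete records")

  bp <- mean_bp(data$sbp1, data$sbp2, data$dbp1, data$dbp2)
  male <- sex == "male"
  th <- thresholds

  flags <- tibble::tibble(
    id = data$id,
    sex = sex,
    wc_abn = data$wc_cm >= ifelse(male, th$wc_male, th$wc_female),
    fpg_abn = data$fpg_mgdl >= th$fpg | as.logical(data$treat_glucose),
    bp_abn = bp$sbp >= th$sbp | bp$dbp >= th$dbp | as.logical(data$treat_bp),
    tg_abn = data$tg_mgdl >= th$tg | as.logical(data$treat_tg),
    hdl_abn = data$hdl_mgdl <= ifelse(male, th$hdl_male, th$hdl_female) |
      as.logical(data$treat_hdl)
  )
  flags$count <- rowSums(flags[, c("wc_abn", "fpg_abn", "bp_abn", "tg_abn",
                                   "hdl_abn")])
  flags$msyn <- flags$count >= 3
  flags
}

#' Distribution of abnormal-component counts
#'
#' Tabulates subjects carrying 0, 1, 2 or >= 3 abnormal ATP III components,
#' the partition used to report syndrome burden.
#'
#' @param flags Output of [classify_atp3()].
#' @return A tibble with columns `components` (`"0"`, `"1"`, `"2"`, `">=3"`),
#'   `n`, `pct`.
#' @export
component_distribution <- function(flags) {
  require_columns(flags, "count", "component_distribution")
  if (!nrow(flags)) abort("component_distribution(): empty cohort")
  lvls <- c("0", "1", "2", ">=3")
  cls <- factor(ifelse(flags$count >= 3, ">=3", as.character(flags$count)),
                levels = lvls)
  tibble::tibble(
    components = lvls,
    n = as.integer(table(cls)),
    pct = 100 * as.integer(table(cls)) / nrow(flags)
  )
}
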