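# Anthropometric index calculators.
#
# Unit conventions: the cohort table stores height/WC in cm, weight in kg and
# biochemistry in mg/dL. Each calculator converts internally to the units its
# formula is defined in (ABSI and the conicity index use metres; VAI uses
# mmol/L for TG and HDL-C).

#' Body mass index
#'
#' @param weight Body weight in kg.
#' @param height Standing height in cm.
#' @return BMI in kg/m^2.
#' @examples
#' compute_bmi(85, 175)
#' @export
compute_bmi <- function(weight, height) {
  check_positive(weight = weight, height = height)
  weight / (height / 100)^2
}

#' Waist-to-height ratio
#'
#' Dimensionless, so any common unit for the two lengths gives the same value.
#'
#' @param wc Waist circumference.
#' @param height Standing height, in the same unit as `wc`.
#' @return WHtR (dimensionless).
#' @export
compute_whtr <- function(wc, height) {
  check_positive(wc = wc, height = height)
  wc / height
}

#' A Body Shape Index (ABSI)
#'
#' WC normalised by the allometric expectation from height and BMI:
#' `WC_m / (height_m^0.5 * BMI^(2/3))`. High ABSI flags a waist that is large
#' for a given height and BMI.
#'
#' @param wc Waist circumference in cm.
#' @param height Standing height in cm.
#' @param bmi BMI in kg/m^2.
#' @return ABSI in m^(11/6) kg^(-2/3).
#' @export
compute_absi <- function(wc, height, bmi) {
  check_positive(wc = wc, height = height, bmi = bmi)
  (wc / 100) / (sqrt(height / 100) * bmi^(2 / 3))
}

#' Body Roundness Index (BRI)
#'
#' Eccentricity-based transform of the waist-to-height geometry:
#' `364.2 - 365.5 * sqrt(1 - (WC/(2*pi))^2 / (0.5*height)^2)`.
#' Ranges from -1.3 (a vanishing waist) towards 364.2 as the waist approaches
#' the spherical bound `WC = pi * height`.
#'
#' @param wc Waist circumference in cm.
#' @param height Standing height in cm.
#' @return BRI (dimensionless).
#' @export
compute_bri <- function(wc, height) {
  check_positive(wc = wc, height = height)
  if (any(wc > pi * height)) {
    abort("compute_bri(): waist exceeds spherical bound (wc > pi * height)")
  }
  ratio2 <- (wc / (2 * pi))^2 / (0.5 * height)^2
  364.2 - 365.5 * sqrt(pmax(1 - ratio2, 0))
}

#' Conicity index
#'
#' WC relative to the circumference of a cylinder holding the subject's mass:
#' `WC_m / (0.109 * sqrt(weight / height_m))`.
#'
#' @param wc Waist circumference in cm.
#' @param weight Body weight in kg.
#' @param height Standing height in cm.
#' @return Conicity index in m^(3/2) kg^(-1/2).
#' @export
compute_ci <- function(wc, weight, height) {
  check_positive(wc = wc, weight = weight, height = height)
  (wc / 100) / (0.109 * sqrt(weight / (height / 100)))
}

#' Visceral Adiposity Index (VAI)
#'
#' Sex-specific composite of waist, BMI and fasting lipids:
#' males `(WC / (39.68 + 1.88*BMI)) * (TG/1.03) * (1.31/HDL)`,
#' females `(WC / (36.58 + 1.89*BMI)) * (TG/0.81) * (1.52/HDL)`,
#' with TG and HDL-C in mmol/L. Calibrated so a metabolically average subject
#' scores 1.
#'
#' @param sex `"male"` or `"female"` (vectorised).
#' @param wc Waist circumference in cm.
#' @param bmi BMI in kg/m^2.
#' @param tg Fasting triglycerides in mmol/L.
#' @param hdl HDL cholesterol in mmol/L.
#' @return VAI (dimensionless).
#' @export
compute_vai <- function(sex, wc, bmi, tg, hdl) {
  sex <- check_sex(sex)
  check_positive(wc = wc, bmi = bmi, tg = tg, hdl = hdl)
  male <- sex == "male"
  waist_term <- ifelse(male,
    wc / (39.68 + 1.88 * bmi),
    wc / (36.58 + 1.89 * bmi)
  )
  tg_term <- ifelse(male, tg / 1.03, tg / 0.81)
  hdl_term <- ifelse(male, 1.31 / hdl, 1.52 / hdl)
  waist_term * tg_term * hdl_term
}

#' Convert mg/dL to mmol/L
#'
#' Uses the standard molar-mass divisors: glucose 18.016, triglycerides 88.57,
#' cholesterol (incl. HDL-C) 38.67. 100 mg/dL glucose is 5.55 mmol/L;
#' 150 mg/dL TG is 1.69 mmol/L.
#'
#' @param value Concentration in mg/dL (non-negative).
#' @param analyte One of `"glucose"`, `"tg"`, `"hdl"`, `"cholesterol"`.
#' @return Concentration in mmol/L.
#' @export
mgdl_to_mmol <- function(value, analyte = c("glucose", "tg", "hdl", "cholesterol")) {
  analyte <- match.arg(analyte)
  if (any(!is.finite(value)) || any(value < 0)) {
    abort("mgdl_to_mmol(): value must be finite and >= 0")
  }
  divisor <- switch(analyte,
    glucose = 18.016,
    tg = 88.57,
    hdl = ,
    cholesterol = 38.67
  )
  value / divisor
}

#' Compute the seven-index panel for a cohort
#'
#' Takes a cohort table in the pipeline schema (see [read_cohort()]) and
#' returns one row per subject with all seven indices. WC is passed through
#' unchanged; VAI converts TG and HDL-C to mmol/L internally.
#'
#' @param data A data frame with columns `id`, `sex`, `height_cm`, `weight_kg`,
#'   `wc_cm`, `tg_mgdl`, `hdl_mgdl`.
#' @return A tibble with columns `id`, `sex`, `bmi`, `wc`, `whtr`, `absi`,
#'   `bri`, `ci`, `vai`.
#' @examples
#' compute_indices(fixture_cohort())
#' @export
compute_indices <- function(data) {
  require_columns(data, c("id", "sex", "height_cm", "weight_kg", "wc_cm",
                          "tg_mgdl", "hdl_mgdl"), "compute_indices")
  out <- tryCatch(
    dplyr::transmute(data,
      id = .data$id,
      sex = .data$sex,
      bmi = compute_bmi(.data$weight_kg, .data$height_cm),
      wc = .data$wc_cm,
      whtr = compute_whtr(.data$wc_cm, .data$height_cm),
      absi = compute_absi(.data$wc_cm, .data$height_cm, .data$bmi),
      bri = compute_bri(.data$wc_cm, .data$height_cm),
      ci = compute_ci(.data$wc_cm, .data$weight_kg, .data$height_cm),
      vai = compute_vai(.data$sex, .data$wc_cm, .data$bmi,
                        mgdl_to_mmol(.data$tg_mgdl, "tg"),
                        mgdl_to_mmol(.data$hdl_mgdl, "hdl"))
    ),
    error = function(e) {
      abort(paste0("compute_indices(): ", conditionMessage(e),
                   " [ids: ", paste(head(data$id, 5), collapse = ", "), " ...]"))
    }
  )
  tibble::as_tibble(out)
}

# -- internal validators ------------------------------------------------------

check_positive <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (any(!is.finite(v)) || any(v <= 0)) {
      abort(sprintf("domain error: '%s' must be finite and > 0", nm))
    }
  }
  invisible(TRUE)
}

check_sex <- function(sex) {
  sex <- as.character(sex)
  bad <- !sex %in% c("male", "female")
  if (any(bad)) {
    abort(sprintf("unknown sex value(s): %s",
                  paste(unique(sex[bad]), collapse = ", ")))
  }
  sex
}

require_columns <- function(data, cols, fn) {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("%s(): missing required column(s): %s",
                  fn, paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}
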