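# Synthetic cohorts.
#
# Two generators: a binormal score model with a closed-form AUC (the
# known-truth harness for the ROC engine), and a full participant-level
# cohort whose per-sex, per-MSyn-status index distributions are parameterised
# from published sex-stratified summary statistics. The cohort generator uses
# a latent MSyn-prone mixture and calibrates the biomarker shift between the
# two subpopulations by bisection so the realised ATP III prevalence hits the
# requested target.

#' Closed-form AUC of a binormal score model
#'
#' For cases `N(mu1, sigma1^2)` and controls `N(mu0, sigma0^2)` the AUC is
#' `pnorm((mu1 - mu0) / sqrt(sigma0^2 + sigma1^2))`.
#'
#' @param mu0,mu1 Control and case means.
#' @param sigma0,sigma1 Control and case SDs (> 0).
#' @return AUC as a proportion.
#' @export
analytic_auc_binormal <- function(mu0, mu1, sigma0 = 1, sigma1 = 1) {
  check_positive(sigma0 = sigma0, sigma1 = sigma1)
  pnorm((mu1 - mu0) / sqrt(sigma0^2 + sigma1^2))
}

#' Draw binormal scores with known truth
#'
#' @inheritParams analytic_auc_binormal
#' @param n0,n1 Control and case sample sizes.
#' @param seed Integer seed (reproducible draws).
#' @return A tibble with columns `score` and `label` (`TRUE` = case).
#' @export
generate_binormal <- function(n0, n1, mu0 = 0, mu1 = 1,
                              sigma0 = 1, sigma1 = 1, seed = 1) {
  stopifnot(n0 >= 1, n1 >= 1)
  check_positive(sigma0 = sigma0, sigma1 = sigma1)
  withr::with_seed(seed, {
    tibble::tibble(
      score = c(rnorm(n0, mu0, sigma0), rnorm(n1, mu1, sigma1)),
      label = rep(c(FALSE, TRUE), c(n0, n1))
    )
  })
}

#' Specification for the synthetic participant cohort
#'
#' Defaults emulate a sex-stratified adult cohort: the per-sex, per-status
#' waist and BMI means/SDs and the latent MSyn-prone proportions match the
#' published stratified summary tables this package's reporting mirrors
#' (overall prevalence 42.5%; 54.2% male). Biomarker distributions are
#' realistic first/second-moment choices; their prone/non-prone gap is the
#' calibration handle.
#'
#' @param n Cohort size.
#' @param sex_ratio Proportion male.
#' @param target_prevalence Desired ATP III MSyn prevalence.
#' @param prone_male,prone_female Latent MSyn-prone probabilities per sex
#'   (rescaled with `target_prevalence`).
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 756, sex_ratio = 410 / 756,
                        target_prevalence = 0.425,
                        prone_male = 0.385, prone_female = 0.471,
                        seed = 1) {
  if (target_prevalence <= 0 || target_prevalence >= 1) {
    abort("cohort_spec(): target_prevalence must be in (0, 1)")
  }
  scale <- target_prevalence / 0.425
  spec <- list(
    n = n, sex_ratio = sex_ratio, target_prevalence = target_prevalence,
    prone = c(male = min(0.99, prone_male * scale),
              female = min(0.99, prone_female * scale)),
    # height (cm), status-invariant; waist/BMI per sex x latent status
    height = list(male = c(mean = 172, sd = 6), female = c(mean = 159, sd = 6)),
    anthro = list(
      male = list(prone = list(wc = c(107.8, 11.5), bmi = c(30.6, 4.2)),
                  non = list(wc = c(93.44, 11.34), bmi = c(25.9, 4.5))),
      female = list(prone = list(wc = c(100.98, 12.56), bmi = c(34.2, 6.0)),
                    non = list(wc = c(84.31, 12.65), bmi = c(27.0, 5.9)))
    ),
    # correlations among (height, bmi, wc) latent normals
    cor_bmi_wc = 0.8, cor_height_wc = 0.2,
    biomarkers = list(
      fpg = list(non = c(92, 13), prone = c(115, 30)),
      tg = list(non = c(meanlog = log(105), sdlog = 0.45),
                prone = c(meanlog = log(175), sdlog = 0.45)),
      hdl = list(male = list(non = c(46, 9), prone = c(39, 8)),
                 female = list(non = c(55, 11), prone = c(46, 9))),
      sbp = list(non = c(118, 13), prone = c(133, 15)),
      dbp = list(non = c(75, 9), prone = c(85, 10)),
      bp_cor = 0.7,
      tc = c(185, 35)
    ),
    treat = list(prone = c(glucose = 0.12, bp = 0.15, tg = 0.04, hdl = 0.02),
                 non = c(glucose = 0.02, bp = 0.03, tg = 0.01, hdl = 0.005)),
    bounds = list(height = c(140, 200), weight = c(35, 160), wc = c(50, 160)),
    seed = seed
  )
  structure(spec, class = "cohort_spec")
}

#' Generate a synthetic participant cohort
#'
#' Draws correlated (height, BMI, waist) anthropometry per sex and latent
#' MSyn-prone status from truncated multivariate normals, log-normal
#' triglycerides, normal HDL-C and FPG, bivariate-normal blood pressure, and
#' treatment flags. The prone/non-prone biomarker mean gap is scaled by a
#' factor `delta` found by bisection (at most 25 iterations) so that the
#' realised ATP III prevalence is within 0.005 of the target; an unreachable
#' target is an error.
#'
#' @param spec A [cohort_spec()].
#' @param calibrate Bisect the biomarker shift to hit the target prevalence
#'   (default `TRUE`); if `FALSE` the nominal gap (`delta = 1`) is used.
#' @return A tibble in the pipeline CSV schema (see [read_cohort()]), with
#'   attributes `delta` (calibrated shift), `prevalence` (realised) and
#'   `prone` (the latent status vector).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 500, seed = 7))
#' mean(classify_atp3(cohort)$msyn)
#' @export
generate_cohort <- function(spec = cohort_spec(), calibrate = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n
    n_male <- round(n * spec$sex_ratio)
    sex <- rep(c("male", "female"), c(n_male, n - n_male))
    prone <- rbinom(n, 1, spec$prone[sex]) == 1

    anthro <- draw_anthropometry(sex, prone, spec)

    # standardised biomarker draws; delta only moves the means they attach to
    z <- list(
      fpg = rnorm(n), tg = rnorm(n), hdl = rnorm(n),
      bp = bivariate_z(n, spec$biomarkers$bp_cor)
    )
    tc <- rnorm(n, spec$biomarkers$tc[1], spec$biomarkers$tc[2])
    u_treat <- matrix(runif(4 * n), ncol = 4,
                      dimnames = list(NULL, c("glucose", "bp", "tg", "hdl")))
    demo <- draw_demographics(n)

    assemble <- function(delta) {
      bio <- realise_biomarkers(sex, prone, z, delta, spec)
      tp <- t(vapply(seq_len(n), function(i) {
        p <- if (prone[i]) spec$treat$prone else spec$treat$non
        u_treat[i, ] < p
      }, logical(4)))
      tibble::tibble(
        id = sprintf("SYN%05d", seq_len(n)),
        sex = sex,
        age = demo$age,
        height_cm = anthro$height, weight_kg = anthro$weight,
        wc_cm = anthro$wc,
        sbp1 = bio$sbp, sbp2 = bio$sbp2,
        dbp1 = bio$dbp, dbp2 = bio$dbp2,
        fpg_mgdl = bio$fpg, tg_mgdl = bio$tg, hdl_mgdl = bio$hdl,
        tc_mgdl = pmax(tc, 80),
        treat_glucose = tp[, 1], treat_bp = tp[, 2],
        treat_tg = tp[, 3], treat_hdl = tp[, 4],
        smoking = demo$smoking, education = demo$education,
        income = demo$income, marital = demo$marital
      )
    }
    prevalence_at <- function(delta) {
      mean(suppressMessages(classify_atp3(assemble(delta)))$msyn)
    }

    delta <- 1
    if (calibrate) {
      delta <- bisect_delta(prevalence_at, spec$target_prevalence,
                            lo = 0, hi = 4, tol = 0.005, max_iter = 25)
    }
    cohort <- assemble(delta)
    structure(cohort,
              delta = delta,
              prevalence = mean(suppressMessages(classify_atp3(cohort))$msyn),
              prone = prone)
  })
}

#' Deterministic 12-subject fixture cohort
#'
#' Hand-constructed records straddling the ATP III boundaries: an exact
#' female waist threshold, a treatment-only abnormality, an underweight
#' subject with no abnormal components, just-below-threshold values, and
#' full-house cases. [fixture_expected()] carries the frozen index panel and
#' classification for regression testing.
#'
#' @return A tibble in the pipeline CSV schema.
#' @export
fixture_cohort <- function() {
  tibble::tribble(
    ~id, ~sex, ~age, ~height_cm, ~weight_kg, ~wc_cm, ~sbp1, ~sbp2, ~dbp1, ~dbp2,
    ~fpg_mgdl, ~tg_mgdl, ~hdl_mgdl, ~tc_mgdl,
    ~treat_glucose, ~treat_bp, ~treat_tg, ~treat_hdl,
    "S01", "male",   45, 175, 85,  98.5, 130, 130, 85, 85, 100,   150,   38.67, 180, FALSE, FALSE, FALSE, FALSE,
    "S02", "female", 28, 165, 45,  62,   100, 100, 60, 60,  80,    70,   65,    150, FALSE, FALSE, FALSE, FALSE,
    "S03", "female", 52, 160, 70,  88,   118, 122, 76, 84,  90,   100,   55,    170, FALSE, FALSE, FALSE, FALSE,
    "S04", "male",   61, 180, 90, 100,   120, 120, 80, 80,  90,   100,   50,    190, FALSE, TRUE,  FALSE, FALSE,
    "S05", "male",   50, 170, 95, 103,   135, 125, 90, 80, 101,   151,   40,    210, FALSE, FALSE, FALSE, FALSE,
    "S06", "female", 38, 155, 80,  95,   128, 128, 84, 84,  99,   149,   50,    185, FALSE, FALSE, FALSE, FALSE,
    "S07", "male",   24, 178, 72,  84,   118, 118, 76, 76,  95,   120,   45,    160, FALSE, FALSE, FALSE, FALSE,
    "S08", "female", 58, 170, 90, 102,   132, 128, 86, 82, 105,   160,   42,    220, FALSE, FALSE, FALSE, FALSE,
    "S09", "male",   42, 165, 78, 101.9, 129, 129, 84, 84,  99.9, 149.9, 40.1,  175, FALSE, FALSE, FALSE, FALSE,
    "S10", "female", 35, 158, 62,  80,   110, 110, 70, 70, 100,    80,   60,    165, TRUE,  FALSE, FALSE, FALSE,
    "S11", "male",   55, 185, 110, 115,  140, 140, 95, 95, 130,   250,   35,    240, FALSE, FALSE, FALSE, FALSE,
    "S12", "female", 47, 162, 58,  75,   124, 126, 80, 84,  92,   155,   48,    195, FALSE, FALSE, FALSE, FALSE
  ) |>
    dplyr::mutate(smoking = "non-smoker", education = "<BSc",
                  income = "350-575", marital = "married")
}

# -- internal -----------------------------------------------------------------

draw_anthropometry <- function(sex, prone, spec) {
  n <- length(sex)
  cm <- matrix(c(1, 0, spec$cor_height_wc,
                 0, 1, spec$cor_bmi_wc,
                 spec$cor_height_wc, spec$cor_bmi_wc, 1), 3, 3)
  out <- matrix(NA_real_, n, 3)  # height, bmi -> weight, wc
  todo <- seq_len(n)
  b <- spec$bounds
  for (attempt in 1:100) {
    if (!length(todo)) break
    z <- MASS::mvrnorm(length(todo), mu = c(0, 0, 0), Sigma = cm)
    z <- matrix(z, ncol = 3)
    sx <- sex[todo]; pr <- ifelse(prone[todo], "prone", "non")
    h <- numeric(length(todo)); bmi <- h; wc <- h
    for (i in seq_along(todo)) {
      hs <- spec$height[[sx[i]]]
      an <- spec$anthro[[sx[i]]][[pr[i]]]
      h[i] <- hs["mean"] + hs["sd"] * z[i, 1]
      bmi[i] <- an$bmi[1] + an$bmi[2] * z[i, 2]
      wc[i] <- an$wc[1] + an$wc[2] * z[i, 3]
    }
    w <- bmi * (h / 100)^2
    ok <- h >= b$height[1] & h <= b$height[2] &
      w >= b$weight[1] & w <= b$weight[2] &
      wc >= b$wc[1] & wc <= b$wc[2] & wc < pi * h & bmi > 10
    out[todo[ok], ] <- cbind(h[ok], w[ok], wc[ok])
    todo <- todo[!ok]
  }
  if (length(todo)) abort("generate_cohort(): truncation resampling failed")
  list(height = out[, 1], weight = out[, 2], wc = out[, 3])
}

bivariate_z <- function(n, rho) {
  z1 <- rnorm(n); z2 <- rnorm(n)
  cbind(z1, rho * z1 + sqrt(1 - rho^2) * z2)
}

# Interpolate prone means/SDs between the non-prone baseline (delta = 0) and
# the nominal prone component (delta = 1); delta > 1 widens the gap.
interp <- function(non, pro, delta) non + delta * (pro - non)

realise_biomarkers <- function(sex, prone, z, delta, spec) {
  n <- length(sex)
  bm <- spec$biomarkers
  pick <- function(par) {  # par: list(non=, prone=) of c(mean, sd)
    m <- ifelse(prone, interp(par$non[1], par$prone[1], delta), par$non[1])
    s <- ifelse(prone, pmax(interp(par$non[2], par$prone[2], delta), 1e-6),
                par$non[2])
    cbind(m, s)
  }
  fpg_ms <- pick(bm$fpg)
  sbp_ms <- pick(bm$sbp)
  dbp_ms <- pick(bm$dbp)
  hdl_ms <- t(vapply(seq_len(n), function(i) {
    par <- bm$hdl[[sex[i]]]
    if (prone[i]) {
      c(interp(par$non[1], par$prone[1], delta),
        max(interp(par$non[2], par$prone[2], delta), 1e-6))
    } else par$non
  }, numeric(2)))
  tg_ml <- ifelse(prone,
                  interp(bm$tg$non["meanlog"], bm$tg$prone["meanlog"], delta),
                  bm$tg$non["meanlog"])
  sbp <- pmax(sbp_ms[, 1] + sbp_ms[, 2] * z$bp[, 1], 70)
  dbp <- pmax(dbp_ms[, 1] + dbp_ms[, 2] * z$bp[, 2], 40)
  list(
    fpg = pmax(fpg_ms[, 1] + fpg_ms[, 2] * z$fpg, 50),
    tg = exp(tg_ml + bm$tg$non["sdlog"] * z$tg),
    hdl = pmax(hdl_ms[, 1] + hdl_ms[, 2] * z$hdl, 10),
    sbp = round(sbp), sbp2 = round(sbp + 2),
    dbp = round(dbp), dbp2 = round(dbp - 2)
  )
}

bisect_delta <- function(f, target, lo, hi, tol, max_iter) {
  f_lo <- f(lo); f_hi <- f(hi)
  if (target < f_lo - tol || target > f_hi + tol) {
    abort(sprintf(
      "generate_cohort(): target prevalence %.3f unreachable (range %.3f-%.3f)",
      target, f_lo, f_hi))
  }
  if (abs(f_lo - target) <= tol) return(lo)
  if (abs(f_hi - target) <= tol) return(hi)
  mid <- (lo + hi) / 2
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- f(mid)
    if (abs(f_mid - target) <= tol) return(mid)
    if (f_mid < target) lo <- mid else hi <- mid
  }
  mid
}

draw_demographics <- function(n) {
  age_breaks <- list(c(20, 34), c(35, 44), c(45, 54), c(55, 65), c(65, 80))
  age_p <- c(0.323, 0.290, 0.235, 0.108, 0.044)
  bin <- sample(seq_along(age_p), n, replace = TRUE, prob = age_p)
  age <- vapply(bin, function(b) {
    round(runif(1, age_breaks[[b]][1], age_breaks[[b]][2]))
  }, numeric(1))
  list(
    age = age,
    smoking = sample(c("non-smoker", "current", "former"), n, TRUE,
                     prob = c(0.278, 0.328, 0.394)),
    education = sample(c("<BSc", ">=BSc"), n, TRUE, prob = c(0.687, 0.313)),
    income = sample(c("<350", "350-575", ">=800"), n, TRUE,
                    prob = c(0.324, 0.507, 0.169)),
    marital = sample(c("married", "single"), n, TRUE, prob = c(0.792, 0.208))
  )
}

#' Frozen expectations for the fixture cohort
#'
#' Index panel and ATP III classification for [fixture_cohort()], frozen from
#' direct single-formula evaluation (values to 6 decimals). Serves as the
#' regression baseline for the full pipeline.
#'
#' @return A list with tibbles `indices` and `flags`.
#' @export
fixture_expected <- function() {
  indices <- tibble::tribble(
    ~id, ~sex, ~bmi, ~wc, ~whtr, ~absi, ~bri, ~ci, ~vai,
    "S01", "male",   27.755102,  98.5, 0.562857, 0.081225, 4.614007, 1.296640, 2.309673,
    "S02", "female", 16.528926,  62.0, 0.375758, 0.074385, 1.323824, 1.089183, 0.806616,
    "S03", "female", 27.343750,  88.0, 0.550000, 0.076651, 4.344815, 1.220583, 1.485264,
    "S04", "male",   27.777778, 100.0, 0.555556, 0.081264, 4.460345, 1.297444, 1.208441,
    "S05", "male",   32.871972, 103.0, 0.605882, 0.076983, 5.561674, 1.264077, 2.127641,
    "S06", "female", 33.298647,  95.0, 0.612903, 0.073724, 5.723186, 1.213160, 2.330772,
    "S07", "male",   22.724404,  84.0, 0.471910, 0.078477, 2.847124, 1.211704, 1.509498,
    "S08", "female", 31.141869, 102.0, 0.600000, 0.079034, 5.427841, 1.286106, 3.335762,
    "S09", "male",   28.650138, 101.9, 0.617576, 0.084726, 5.831748, 1.359698, 2.261232,
    "S10", "female", 24.835763,  80.0, 0.506329, 0.074767, 3.478280, 1.171645, 1.046373,
    "S11", "male",   32.140248, 115.0, 0.621622, 0.083640, 5.926442, 1.368236, 4.556605,
    "S12", "female", 22.100290,  75.0, 0.462963, 0.074824, 2.690501, 1.149948, 2.532569
  )
  flags <- tibble::tribble(
    ~id, ~wc_abn, ~fpg_abn, ~bp_abn, ~tg_abn, ~hdl_abn, ~count, ~msyn,
    "S01", FALSE, TRUE,  TRUE,  TRUE,  TRUE,  4, TRUE,
    "S02", FALSE, FALSE, FALSE, FALSE, FALSE, 0, FALSE,
    "S03", TRUE,  FALSE, FALSE, FALSE, FALSE, 1, FALSE,
    "S04", FALSE, FALSE, TRUE,  FALSE, FALSE, 1, FALSE,
    "S05", TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  5, TRUE,
    "S06", TRUE,  FALSE, FALSE, FALSE, TRUE,  2, FALSE,
    "S07", FALSE, FALSE, FALSE, FALSE, FALSE, 0, FALSE,
    "S08", TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  5, TRUE,
    "S09", FALSE, FALSE, FALSE, FALSE, FALSE, 0, FALSE,
    "S10", FALSE, TRUE,  FALSE, FALSE, FALSE, 1, FALSE,
    "S11", TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  5, TRUE,
    "S12", FALSE, FALSE, FALSE, TRUE,  TRUE,  2, FALSE
  )
  list(indices = indices, flags = flags)
}
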