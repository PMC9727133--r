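---
title: "Screening-index evaluation for metabolic syndrome: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening-index evaluation for metabolic syndrome: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msynscreen)
```

`msynscreen` evaluates seven anthropometric indices — BMI, waist
circumference (WC), waist-to-height ratio (WHtR), A Body Shape Index (ABSI),
Body Roundness Index (BRI), conicity index (CI) and Visceral Adiposity Index
(VAI) — as screening markers for metabolic syndrome (MSyn) under the NCEP
ATP III definition. This vignette explains the models, the numerical
choices, and what the synthetic cohort does and does not emulate.

## Index calculators and units

The cohort table stores height and WC in cm, weight in kg and biochemistry
in mg/dL; each calculator converts internally. ABSI and CI use metres; WHtR
and BRI are ratio-based and unit-invariant; VAI takes triglycerides and
HDL-C in mmol/L (divisors 88.57 and 38.67; glucose uses 18.016).

Two definitional points deserve note:

* **VAI denominator.** VAI is widely printed with ambiguous precedence,
  `WC/39.68 − 1.88·BMI`, which read literally is negative for typical
  adults. The original definition is `WC / (39.68 + 1.88·BMI)` for men and
  `WC / (36.58 + 1.89·BMI)` for women, which also makes the index exactly 1
  for a reference subject (`TG = 1.03`, `HDL = 1.31` mmol/L in men). Only
  this physical form is implemented; no literal "−" mode exists because it
  is non-physical.
* **BRI domain.** BRI requires `WC < π·height` (the "spherical bound");
  outside it the square root is undefined. Violations, like any
  non-positive height/weight/WC, raise errors rather than producing NaN —
  silent NaN propagation in a screening pipeline is worse than a hard stop.
  BRI ranges from −1.3 (vanishing waist) to 364.2 at the bound.

Internally everything is computed in double precision; the reporting layer
rounds to the granularity conventional for these indices (2 decimals, ABSI
4, WHtR 3).

## ATP III classification

Five components: WC ≥ 102/88 cm (men/women), FPG ≥ 100 mg/dL, SBP ≥ 130 or
DBP ≥ 85 mmHg (blood pressure is the mean of the two recorded readings),
TG ≥ 150 mg/dL, HDL-C ≤ 40/50 mg/dL. All comparisons are **inclusive** at
the printed threshold, including HDL's "≤" (some ATP III statements print
"<"; we follow the inclusive wording, and the thresholds object lets a user
emulate either). Drug treatment for a component makes it abnormal regardless
of the measured value; treatment alone suffices for the blood-pressure
component (no additional hypertension-history requirement, which the data
dictionary could not distinguish). Diagnosis is ≥ 3 abnormal components.

Missing component inputs exclude a record listwise; the reader
(`read_cohort()`) routes every exclusion to a log with a reason, so the
analysed records plus the log always partition the input.

## ROC, AUC and Youden cutoffs

The positivity rule is `score > c`: one operating point per unique observed
value plus a `-Inf` point, so the curve always contains the (sens 1, spec 0)
corner. The trapezoidal AUC over (1−specificity, sensitivity) then equals
the Mann–Whitney estimate `(#(pos > neg) + ½#(ties)) / (n₁n₀)` exactly, a
property the test suite checks against brute-force pair counting on hundreds
of tied instances.

Cutoffs are reported as observed score values with the "greater than"
convention, without midpoint interpolation — reported cutoffs are then always
realisable measurements. At equal Youden J the tie breaks towards higher
sensitivity, then the smaller threshold: in a screening context a missed
case costs more than a false positive. For ABSI, whose AUC hovers near
chance, J is nearly flat and reported cutoffs are accordingly unstable —
that instability is real, not numerical.

Three AUC confidence intervals are available: DeLong (default; placement
value variance, assumption-free), Hanley–McNeil (exponential-model
approximation, closer to legacy software output), and a stratified
percentile bootstrap (2,000 replicates, seed required). Analytic intervals
are Wald, clipped to [0, 1]. Sensitivity/specificity at the cutoff get
Wilson intervals. AUC bands are closed on the left (0.80 is "good"):
≥ 0.9 excellent, 0.8–0.9 good, 0.7–0.8 fair, 0.6–0.7 poor, < 0.6 failed,
with a warning below 0.5.

## The synthetic cohort

Participant-level data for cohorts of this kind are typically restricted, so
the generator emulates the *published* statistical structure and nothing
more:

* A latent MSyn-prone indicator per subject (men 38.5%, women 47.1%,
  rescaled if a different target prevalence is requested; 54.2% male).
* Per sex and latent status, (height, BMI, WC) from a trivariate normal
  with the published per-status WC and BMI means/SDs, corr(BMI, WC) = 0.8,
  corr(height, WC) = 0.2, heights 172 ± 6 / 159 ± 6 cm (adult Middle-East
  means; status-invariant). Weight is derived as BMI·height². Draws are
  truncated by resampling to height 140–200 cm, weight 35–160 kg, WC
  50–160 cm — bounds that also keep BRI inside its domain.
* Biomarkers per latent status: normal FPG and HDL-C, log-normal TG,
  bivariate-normal SBP/DBP (ρ = 0.7), plus small treatment-flag
  probabilities. These non-anthropometric parameters are realistic
  first/second-moment choices, not published values, and they are the
  calibration handle: the prone/non-prone mean gap is scaled by a factor δ
  found by bisection (≤ 25 iterations on a fixed set of standardised draws,
  so the search is deterministic and monotone) until the realised ATP III
  prevalence is within 0.005 of the target; an unreachable target errors.
* Demographics are sampled from the published marginal frequencies and used
  only by descriptives.

What this reproduces: first and second moments of the index distributions by
sex and status, the target prevalence, and the qualitative AUC ordering —
WC-driven indices (BRI, WHtR, WC) discriminate well, while ABSI, which
normalises WC by BMI^(2/3) and moves little when WC and BMI rise together,
stays near chance. What it does **not** reproduce: the true joint dependence
between anthropometry and biomarkers (only a one-factor latent mixture; no
copulas — richer structure would be invented, since only means/SDs are
published), component-wise prevalences beyond what calibration induces, and
any sampling-design artefacts of outpatient recruitment. Passing tests on
this cohort therefore validate the *machinery* and the qualitative ranking,
not any exact published AUC.

The binormal generator is the known-truth counterpart: AUC has the closed
form Φ((μ₁−μ₀)/√(σ₀²+σ₁²)), and for equal variances the Youden-optimal
cutoff is (μ₀+μ₁)/2. Empirical AUC converges at the usual √n rate; the
*argmax* cutoff converges at the slower cube-root rate, so cutoff-recovery
checks use n = 50,000 and a 0.05·σ tolerance while AUC checks use
3 Hanley–McNeil SEs at n = 20,000.

## Problem sizes and determinism

The test suite uses 500 brute-force ROC instances (n ≤ 30, with ties), 1,000
random records for classifier monotonicity and panel consistency, 10,000
subjects for generator moment checks, a 5,000-subject cohort for the AUC
ranking property, and the binormal sizes above — sizes at which Monte-Carlo
error is far below the assertion tolerances while the whole suite runs in
well under a minute. All randomness flows through explicit integer seeds
(`withr::with_seed`); generation, classification and reporting are
deterministic given a seed, and the acceptance script threads its `--seed`
through every stochastic step.

## Known limitations

* Only the ATP III definition is implemented; IDF/JIS variants can be
  approximated by overriding the waist thresholds but harmonised definitions
  with mandatory components cannot.
* Sensitivity/specificity confidence intervals assume independent binomials
  at a fixed cutoff; they ignore cutoff-selection uncertainty.
* The DeLong variance is for a single AUC; paired AUC comparison between two
  indices on the same subjects is not implemented.
* The synthetic cohort's biomarker distributions are plausible but
  unpublished; quantities that depend on them (e.g. VAI's exact AUC) should
  be read as qualitative.
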