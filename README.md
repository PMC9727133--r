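# msynscreen

Anthropometric screening indices for metabolic syndrome (MSyn).

Metabolic syndrome — the clustering of central obesity, hyperglycaemia,
hypertriglyceridaemia, low HDL-C and elevated blood pressure — is routinely
screened with cheap anthropometric surrogates. `msynscreen` evaluates seven of
them as diagnostic markers, stratified by sex:

| index | definition (height/WC in the stated unit) |
|---|---|
| BMI | weight / height_m² (kg/m²) |
| WC | waist circumference (cm) |
| WHtR | WC / height (dimensionless) |
| ABSI | WC_m / (height_m^0.5 · BMI^(2/3)) |
| BRI | 364.2 − 365.5·√(1 − (WC/2π)² / (0.5·height)²) |
| CI | WC_m / (0.109·√(weight/height_m)) |
| VAI | sex-specific composite of WC, BMI, TG and HDL-C (mmol/L) |

The pipeline: compute the index panel from raw anthropometry and fasting
biochemistry, classify MSyn by the NCEP ATP III rule (≥ 3 of 5 abnormal
components, treatment counts as abnormal, thresholds inclusive), then, for
every index and stratum, build the empirical ROC curve against the MSyn label,
estimate the AUC with a 95% CI (DeLong by default; Hanley–McNeil and
stratified bootstrap available), locate the optimal cutoff by Youden's
J = sensitivity + specificity − 1, and band the AUC (≥ 0.9 excellent,
0.8–0.9 good, 0.7–0.8 fair, 0.6–0.7 poor, < 0.6 failed). A synthetic-cohort
generator parameterised from published sex-stratified moments makes every
stage testable without access to restricted participant data.

## Worked example

```r
library(msynscreen)

cohort <- generate_cohort(cohort_spec(n = 2000, seed = 11))
report <- run_analysis(cohort)
glance(report)
#> # A tibble: 1 × 5
#>       n n_excluded msyn_prevalence best_index best_auc
#>   <int>      <int>           <dbl> <chr>         <dbl>
#> 1  2000          0           0.423 vai           0.832

dplyr::filter(tidy(report), stratum == "total")[, c("index","auc","cutoff","youden","band")]
#>   index   auc  cutoff youden band
#> 1 bmi   0.791 29.4    0.469  fair
#> 2 wc    0.787 96.4    0.448  fair
#> 3 bri   0.818  4.82   0.513  good
#> 4 absi  0.543  0.0767 0.0820 failed
#> 5 vai   0.832  2.20   0.525  good
#> 6 ci    0.654  1.28   0.226  poor
#> 7 whtr  0.818  0.572  0.513  good
```

Read: on this synthetic cohort 42.3% of subjects meet the ATP III definition;
BRI, WHtR and VAI discriminate MSyn well (AUC ≈ 0.82–0.83), the waist cutoff
maximising J for BRI is "> 4.82", and ABSI carries almost no signal — the
qualitative ordering reported for real Middle-Eastern cohorts. Single markers
work the same way from vectors:

```r
fit <- evaluate_index(scores, labels)   # msyn_roc_summary
tidy(fit); autoplot(fit)                # one-row tibble; ggplot ROC curve
```

`read_cohort("cohort.csv")` validates a CSV in `cohort_schema()` layout and
logs listwise exclusions; `write_cohort_report()` writes the stratified
tables plus a run manifest. `inst/scripts/run_pipeline.R` wraps simulate /
report for shell use.

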