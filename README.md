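# nephrospan

Life expectancy by kidney-function stratum: CKD-EPI eGFR classification,
KDIGO risk staging, person-year exposure on the age time scale, and Chiang
abridged life tables with confidence intervals — plus a synthetic-cohort
generator with a known mortality surface so the whole chain is testable
without registry access.

## Who this is for

Epidemiologists and biostatisticians who want to report kidney-disease
prognosis as *remaining years of life* rather than hazard ratios: given
person-level records (sex, age, serum creatinine, albumin-to-creatinine
ratio and/or urine dipstick, follow-up time, vital status), the package
produces sex-stratified life-expectancy tables across eGFR × albuminuria
cells or KDIGO risk classes, and difference tables against the healthiest
stratum, each with 95% CIs.

## The statistics at the core

* **Classification.** eGFR from the 2009 CKD-EPI creatinine equation
  `141 · min(Scr/κ,1)^α · max(Scr/κ,1)^-1.209 · 0.993^age · 1.018[female]`;
  categories ≥60 / 45–59 / 30–44 / 15–29 (eGFR < 15, dialysis or transplant
  at entry → excluded). Albuminuria by median ACR (<30 / 30–300 / >300 mg/g)
  or, failing that, median dipstick (negative / trace–1+ / ≥2+); the KDIGO
  2012 matrix maps both to low / moderate / high / very-high risk.
* **Exposure.** Follow-up is split over 5-year age bands from 40 with an open
  80+ band, left-truncated at 40, deaths assigned to the band containing the
  exit age. Band rates are `m_i = D_i / PY_i`.
* **Life table (Chiang).** `q_i = n·m_i / (1 + n(1−a)m_i)` with `a = 0.5`,
  terminal band `L_w = l_w/m_w`; `Var(q_i) = q_i²(1−q_i)/D_i`, a
  delta-method (Silcocks-style) variance `1/(m_w²D_w)` for the open band, and
  `e ± 1.96·se` intervals. Differences between strata combine SEs in
  quadrature.
* **Validation.** The simulator samples exact piecewise-exponential death
  times; `analytic_life_expectancy()` gives the true expectancy in closed
  form, so life-table output is checked by parameter recovery, CI coverage,
  and bootstrap/SE agreement in the test suite.

## Worked example

Simulate a cohort under the calibrated default hazards (24.8 years of true
remaining life at 50 for men with preserved eGFR and no albuminuria), run the
KDIGO-mode analysis for men, and tabulate losses against the low-risk class:

```r
library(nephrospan)
cohort <- sample_cohort(cohort_config(n_per_stratum = 5000, seed = 42),
                        default_hazard_spec())
res <- run_analysis(cohort, grouping = "kdigo", sexes = "male")
tabs <- res$life_tables
names(tabs) <- sub("^male\\|", "", names(tabs))
loss_matrix(tabs, index_ages = 50)
#>      class index_age     e  loss    se ci_lo ci_hi
#>        LOW        50 25.89  0.00 0.000  0.00  0.00
#>   MODERATE        50 19.34  6.55 0.623  5.33  7.77
#>       HIGH        50 15.05 10.83 0.571  9.71 11.95
#>  VERY_HIGH        50  9.41 16.48 0.540 15.42 17.54
```

A 50-year-old man in the very-high-risk class has an estimated 9.4 remaining
years, 16.5 fewer (95% CI 15.4–17.5) than the low-risk class; the low-risk
estimate 25.9 (SE 0.53) covers the generator's true 24.8. Individual tables
print the full Chiang columns:

```r
tabs[["LOW"]]
#> Chiang abridged life table -- stratum: male|LOW
#>   band   D       PY     m     q         l      e  se_e
#>  40-45   7 1684.753 0.004 0.021 100000.00 34.466 0.618
#>  45-50   8 1488.429 0.005 0.027  97943.90 30.137 0.576
#>  ...
#>    80+ 475 2898.227 0.164 1.000  37072.04  6.102 0.280
```

The same pipeline runs from the command line
(`exec/nephrospan simulate|classify|lifetable|report`), writing CSV tables
and a JSON run manifest; `--sensitivity` repeats the analysis excluding
persons with diabetes, hypertension or cardiovascular disease.

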