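---
title: "Life expectancy by kidney-function stratum: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Life expectancy by kidney-function stratum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nephrospan)
```

## The problem

Chronic kidney disease is staged jointly by estimated glomerular filtration
rate (eGFR) and albuminuria, because both carry independent mortality
information. For communicating prognosis, remaining life expectancy is often
more useful than hazard ratios. `nephrospan` implements the full estimation
chain for cohort data: classify each person at baseline, accumulate deaths
and person-years on the age time scale, and convert age-band mortality rates
into abridged life tables with confidence intervals, stratified by sex and
kidney-function stratum. Because population registries are not shippable, the
package pairs the estimator with a synthetic-cohort generator whose true
mortality surface is known in closed form, so every stage is validated by
parameter recovery rather than by fixture files.

## Classification

eGFR comes from the 2009 CKD-EPI creatinine equation,

$$\mathrm{eGFR} = 141 \cdot \min(S_{cr}/\kappa, 1)^{\alpha}
  \cdot \max(S_{cr}/\kappa, 1)^{-1.209} \cdot 0.993^{\mathrm{age}}
  \cdot 1.018[\text{female}],$$

with $\kappa$ = 0.7 (women) / 0.9 (men) and $\alpha$ = −0.329 / −0.411.
Creatinine is mg/dL internally; `read_persons()` converts from µmol/L
(÷ 88.4). The published black-ethnicity factor (×1.159) is implemented but
off by default, since the analyses this package supports do not apply it.
Categories are half-open and exhaustive: ≥60, 45–59, 30–44, 15–29; below 15
the person is excluded from the cohort, as are persons on dialysis or with a
kidney transplant at entry.

Albuminuria uses the albumin-to-creatinine ratio (ACR) when available —
normal < 30 mg/g, mild 30–300 mg/g (boundary values inclusive, a literal
reading of the conventional "30–300" range), heavy > 300 mg/g — otherwise
urine dipstick (negative → normal; trace or 1+ → mild; ≥ 2+ → heavy; readings
above 2+ map to heavy as the monotone extension). Repeated measurements are
summarized by their median. Two scale-specific conventions apply to
even-length lists: ACR, a continuous scale, uses the arithmetic midpoint of
the two middle values; dipstick, an ordinal scale that cannot be
interpolated, uses the lower of the two. Measurements are expected to lie in
the ±6-month window around the index creatinine; `read_persons()` applies the
window when day offsets are present, and a person left with no in-window
measurement is ineligible. When both ACR and dipstick exist, ACR wins.

The KDIGO 2012 prognosis matrix combines the two axes into low / moderate /
high / very-high risk; it is stored as a literal lookup table and tested for
monotonicity along both axes.

## Exposure and the life table

Age is the time scale. Follow-up $[\max(\text{entry}, 40), \text{exit})$ is
cut into 5-year bands from 40 with an open 80+ band; a death is placed in the
band containing the exit age, with deaths at an exact band boundary assigned
to the higher band (one consistent half-open convention). Ages are continuous
throughout; no rounding. Baseline stratum is carried forward over the whole
follow-up — the estimator deliberately does not update kidney function over
time, matching how such registries are analyzed at baseline.

Band rates $m_i = D_i/PY_i$ feed a Chiang abridged life table:

$$q_i = \frac{n_i m_i}{1 + n_i(1-a_i) m_i}, \qquad
  L_i = n_i (l_{i+1} + a_i d_i), \qquad
  L_w = l_w / m_w, \qquad e_i = \frac{\sum_{j \ge i} L_j}{l_i},$$

with $a_i = 0.5$ everywhere — the standard assumption for 5-year adult bands
when deaths are roughly uniform within a band. Variances use Chiang's
$\widehat{Var}(q_i) = q_i^2(1-q_i)/D_i$ (set to 0 when $D_i = 0$, the
estimator's continuous limit) and

$$Var(e_x) = \frac{\sum_{j<w} l_j^2\,[(1-a_j)n_j + e_{j+1}]^2 \widehat{Var}(q_j)
  + l_w^2/(m_w^2 D_w)}{l_x^2}.$$

The terminal term is a delta-method variance for $e_w = 1/m_w$ under Poisson
deaths (a Silcocks-style correction): Chiang's original derivation carries no
open-interval variance, but confidence intervals are reported at age 80, so a
term is required; a stratum with no terminal-band deaths is unreportable and
is skipped with a logged reason rather than silently dropped. Intervals are
normal-approximation $e \pm 1.96\,se$; differences between independent strata
combine as $\sqrt{se_1^2 + se_2^2}$, and a table differenced with itself
returns exactly 0 with CI [0, 0]. No graduation or smoothing of rates is
applied. Expectancies and their standard errors are invariant to the radix.

### Numerical behaviour of the $a = 0.5$ approximation

On counts whose rates equal the true hazards exactly, the table is exact for
a constant hazard (the $m \to q \to L$ chain is self-consistent), and within
1% of the closed-form piecewise-exponential expectancy when closed-band
hazards stay below 0.1/yr *and* the open-band hazard is in a demographic
range (0.05–0.5/yr, i.e. 2–20 remaining years at 80). That second condition
matters: the open band contributes $S_w/\lambda_w$, so an absurdly small
terminal hazard (say 0.002/yr, a 500-year expectancy) multiplies the small
closed-band $q$ bias past any fixed bound. The validation suite therefore
samples terminal hazards from the demographic range. For the calibrated
default strata the deterministic bias at age 50 is ≈ +0.03 years against a
sampling SE of ≈ 0.12 at 100,000 persons, which is why CI coverage of the
true value remains near nominal in the recovery tests.

A closed band whose rate implies $q_i = 1$ (possible once $m_i \gtrsim
0.4$/yr for 5-year bands) would zero the survivorship mid-table; the builder
rejects such strata rather than report a degenerate table.

## The synthetic cohort: what it emulates, and what it does not

Each stratum (sex × eGFR category × albuminuria category) carries a vector of
piecewise-constant hazards over the age bands. Death times are drawn by exact
inverse-CDF sampling on the piecewise-exponential survival function — no
time-stepping, so oracle comparisons carry no discretization bias. Index ages
are uniform on [30, 90), exercising left truncation at 40. Staggered entry
over a multi-year accrual window with a fixed study end is emulated by an
administrative censoring horizon drawn uniformly from [1, 7] years; there is
no loss to follow-up. Ages below 40 reuse the first band's hazard.

Measurements are generated to be consistent with the stratum: serum
creatinine inverts the CKD-EPI equation (closed form — the equation is a
two-piece power law, so root-finding is unnecessary) at a target eGFR drawn
uniformly within the category interval, the open ≥60 category capped at 150
and additionally at the value achievable at the floor creatinine of
0.2 mg/dL, which binds only at advanced ages. Underlying ACR is log-uniform
strictly inside the category bounds with a 5% margin, and repeat measurements
scatter around it log-normally (SD 0.1), so the median stays in-category with
high probability; dipstick-only persons (20%) draw readings from the
category's consistent pool. Comorbidity flags are independent Bernoulli draws
(diabetes 12%, hypertension 38%, cardiovascular disease 8%, near the
population prevalences of a general laboratory cohort).

Default hazards are Gompertz-shaped, $\lambda_i = s\,e^{0.09 (x_i - 40)}$ at
band midpoints (85 for the open band), $\theta = 0.09$/yr being a mortality
doubling time of ≈ 7.7 years. The scale $s$ is calibrated per stratum by
root-finding so that the *exact* expectancy at age 50 equals a published-scale
anchor for that stratum (24.8 years for men with preserved eGFR and no
albuminuria, down to ≈ 5.5 years in the worst strata), making the simulated
world quantitatively plausible. Band hazards are capped at 0.3/yr: sustained
rates beyond that are not observed in human populations and lie outside the
validity domain of the abridged-table $m \to q$ conversion. The cap is part
of the generator's model, applied before calibration.

The generator makes **no** claim of demographic realism beyond these
magnitudes: the joint distribution of age and kidney function, calendar
(period) effects, secular trends, correlated comorbidity–mortality structure
and non-administrative dropout are all absent. A green recovery test
establishes that the estimator recovers known hazard surfaces of realistic
magnitude — not that simulated expectancies equal any particular published
table.

## Reporting pipeline

`run_analysis()` chains classification, exposure aggregation (either the full
eGFR × albuminuria cross or the four KDIGO classes), per-stratum life tables,
and difference tables (reference: no albuminuria within each eGFR category,
or the low-risk class via `loss_matrix()`). The sensitivity switch repeats
the analysis after excluding anyone with diabetes, hypertension or
cardiovascular disease. Every run writes a manifest accounting for each input
person (included / excluded with reason / follow-up entirely before 40) and
is byte-for-byte reproducible given the seed. Strata failing life-table
preconditions appear in a `skipped` table with the precondition that failed.
Configuration files are JSON (the pre-installed stack carries no YAML
parser). The same pipeline is scriptable via the `nephrospan`
simulate/classify/lifetable/report command-line entry point under `exec/`.

## Known limitations

* The Chiang CI is a normal approximation; at very sparse strata (tens of
  deaths) its coverage degrades, which is why under-filled strata are
  refused rather than reported with misleading intervals.
* The $a=0.5$ assumption biases $e$ by a few hundredths of a year under
  realistic hazards; at registry scale (millions of person-years, SEs of
  hundredths) that bias would be material, and a graduated $a_i$ would be the
  next refinement.
* Two printed cells of the published tables this design emulates are
  internally inconsistent at the 0.1-year rounding level (a difference
  computed from unrounded values); the consistency tests assert only cells
  that reproduce by subtraction of the printed expectancies.
* Dipstick medians on an ordinal scale have no unique convention; the
  lower-middle choice here is conservative (never worsens the category on a
  tie) and is flagged as a design decision, not an inference about how any
  particular registry analysis handled ties.
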