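# Shared fixtures and independent oracles.

SCHEME <- age_band_scheme()

# Quadrature oracle for remaining life expectancy under piecewise-constant
# hazards: integrates S(t) = exp(-H(t)) numerically, independent of the
# closed-form recursion in analytic_life_expectancy().
quadrature_expectancy <- function(hazards, scheme, start_age) {
  knots <- c(scheme$start, Inf)
  rate_at <- function(t) hazards[pmax(findInterval(t, scheme$start), 1L)]
  cumhaz <- function(t) {
    vapply(t, function(ti) {
      H <- 0
      lo <- start_age
      for (j in seq_len(scheme$n_bands)) {
        a <- max(lo, if (j == 1) -Inf else knots[j])
        b <- min(ti, knots[j + 1])
        if (b > a) H <- H + hazards[j] * (b - a)
      }
      H
    }, 0)
  }
  surv <- function(t) exp(-cumhaz(t))
  total <- 0
  pieces <- c(start_age, scheme$start[scheme$start > start_age])
  for (j in seq_along(pieces)) {
    lo <- pieces[j]
    hi <- if (j < length(pieces)) pieces[j + 1] else Inf
    total <- total + stats::integrate(surv, lo, hi, rel.tol = 1e-12,
                                      abs.tol = 1e-13)$value
  }
  total
}

# Life table built from exact band rates (deaths/person-years in the exact
# ratio lambda), used to isolate the a = 0.5 approximation from sampling.
exact_rate_table <- function(hazards, scheme, py = 1e9) {
  build_life_table(round(hazards * py), rep(py, scheme$n_bands), scheme)
}

# Minimal valid person record for classification tests.
make_person <- function(id = "p1", sex = "male", index_age = 50,
                        serum_creatinine = 0.9,
                        acr = list(c(10)), dip = list(character(0)),
                        exit_age = 55, died = FALSE,
                        dialysis = FALSE,
                        diabetes = FALSE, hypertension = FALSE, cvd = FALSE) {
  df <- data.frame(
    id = id, sex = sex, index_age = index_age,
    serum_creatinine = serum_creatinine,
    has_diabetes = diabetes, has_hypertension = hypertension, has_cvd = cvd,
    exit_age = exit_age, died = died,
    on_dialysis_or_transplant = dialysis,
    stringsAsFactors = FALSE
  )
  df$acr_values <- acr
  df$dipstick_values <- dip
  df
}

# Small two-stratum hazard spec used across pipeline tests.
small_hazard_spec <- function(scheme = SCHEME) {
  hazard_spec(list(
    "male|GE60.NORMAL" = gompertz_hazards_for_tests(0.004, scheme),
    "male|GE60.MILD"   = gompertz_hazards_for_tests(0.010, scheme)
  ), scheme)
}

# Band hazards calibrated so the exact e(50) equals a target (package internal).
gompertz_hazards_calibrated <- function(target_e50, scheme = SCHEME) {
  nephrospan:::gompertz_band_hazards(target_e50, scheme)
}

gompertz_hazards_for_tests <- function(scale, scheme, theta = 0.08) {
  mids <- ifelse(is.finite(scheme$width), scheme$start + scheme$width / 2,
                 scheme$start + 5)
  pmin(scale * exp(theta * (mids - 40)), 0.3)
}
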