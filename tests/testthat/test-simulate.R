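test_that("hazard_spec validates its strata", {
  expect_error(hazard_spec(list(a = rep(0.1, 3)), SCHEME), "length")
  expect_error(hazard_spec(list(a = c(rep(0.1, 8), -1)), SCHEME), "non-negative")
  expect_error(hazard_spec(list(a = c(rep(0.1, 8), 0)), SCHEME), "terminal")
  sp <- hazard_spec(list(a = rep(0.1, 9)), SCHEME)
  expect_error(analytic_life_expectancy(sp, "missing", 40), "unknown stratum")
})

test_that("analytic_life_expectancy matches hand results and quadrature", {
  sp <- hazard_spec(list(k = rep(0.1, 9)), SCHEME)
  expect_equal(analytic_life_expectancy(sp, "k", 40), 10, tolerance = 1e-12)
  expect_equal(analytic_life_expectancy(sp, "k", 65), 10, tolerance = 1e-12)

  sp2 <- hazard_spec(list(k = c(rep(0, 8), 0.5)), SCHEME)
  expect_equal(analytic_life_expectancy(sp2, "k", 40), 42, tolerance = 1e-12)

  expect_error(analytic_life_expectancy(sp, "k", 41), "band boundary")

  set.seed(55)
  for (rep in 1:5) {
    lam <- c(runif(8, 0, 0.2), runif(1, 0.05, 0.5))
    lam[sample(1:8, 2)] <- 0 # exercise the zero-hazard branch
    sp3 <- hazard_spec(list(k = lam), SCHEME)
    for (age in c(40, 55, 80)) {
      expect_equal(analytic_life_expectancy(sp3, "k", age),
                   quadrature_expectancy(lam, SCHEME, age), tolerance = 1e-9)
    }
  }
})

test_that("zero closed-band hazards produce no deaths before 80", {
  sp <- hazard_spec(list("male|GE60.NORMAL" = c(rep(0, 8), 0.5)), SCHEME)
  cfg <- cohort_config(n_per_stratum = 500, admin_followup_years = Inf, seed = 3)
  p <- sample_cohort(cfg, sp)
  expect_true(all(p$died))
  expect_true(all(p$exit_age[p$died] >= 80))
})

test_that("constant hazard 0.1 yields mean residual life near 10 years", {
  sp <- hazard_spec(list("male|GE60.NORMAL" = rep(0.1, 9)), SCHEME)
  cfg <- cohort_config(n_per_stratum = 20000, admin_followup_years = Inf, seed = 4)
  p <- sample_cohort(cfg, sp)
  expect_true(all(p$died))
  mrl <- mean(p$exit_age - p$index_age)
  expect_equal(mrl, 10, tolerance = 0.03) # MC se ~ 10/sqrt(20000) = 0.07
})

test_that("sample_cohort is byte-identical under the same seed", {
  sp <- small_hazard_spec()
  cfg <- cohort_config(n_per_stratum = 200, seed = 42)
  expect_identical(sample_cohort(cfg, sp), sample_cohort(cfg, sp))
  cfg2 <- cohort_config(n_per_stratum = 200, seed = 43)
  expect_false(identical(sample_cohort(cfg, sp), sample_cohort(cfg2, sp)))
})

test_that("simulated measurements are consistent with the generating stratum", {
  set.seed(1)
  hs <- default_hazard_spec()
  p <- sample_cohort(cohort_config(n_per_stratum = 300, seed = 10), hs)
  expect_true(all(p$index_age >= 30))
  expect_true(all(p$exit_age >= p$index_age))
  # everyone carries at least one albuminuria measurement
  n_meas <- lengths(p$acr_values) + lengths(p$dipstick_values)
  expect_true(all(n_meas > 0))
  # ACR medians sit inside the generating category for ACR-measured persons
  has_acr <- lengths(p$acr_values) > 0
  med <- vapply(p$acr_values[has_acr], stats::median, 0)
  expect_true(mean(categorize_acr(med) == p$true_albuminuria_category[has_acr]) > 0.99)
  # dipstick readings come from the category's pool
  has_dip <- lengths(p$dipstick_values) > 0
  pool_ok <- mapply(function(v, cat) {
    all(v %in% switch(cat, NORMAL = "negative", MILD = c("trace", "1+"),
                      HEAVY = c("2+", "3+")))
  }, p$dipstick_values[has_dip], p$true_albuminuria_category[has_dip])
  expect_true(all(pool_ok))
})

test_that("default_hazard_spec hits its calibration anchors exactly", {
  hs <- default_hazard_spec()
  expect_length(hs$strata, 24)
  anchors <- nephrospan:::default_e50_anchors()
  for (i in seq_len(nrow(anchors))) {
    key <- paste0(anchors$sex[i], "|", anchors$egfr[i], ".", anchors$alb[i])
    expect_equal(analytic_life_expectancy(hs, key, 50), anchors$e50[i],
                 tolerance = 1e-6)
  }
  expect_true(all(vapply(hs$strata, max, 0) <= 0.3 + 1e-12))
})

test_that("unknown stratum key shape is rejected", {
  sp <- hazard_spec(list("badkey" = rep(0.1, 9)), SCHEME)
  cfg <- cohort_config(n_per_stratum = 10, seed = 1)
  expect_error(sample_cohort(cfg, sp), "stratum key")
})
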