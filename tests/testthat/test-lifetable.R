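test_that("mortality_rates divides deaths by person-years and flags empty bands", {
  expect_equal(mortality_rates(10, 1000), 0.01)
  expect_equal(mortality_rates(c(0, 5), c(100, 5)), c(0, 1))
  expect_error(mortality_rates(c(1, 0), c(100, 0)), "band\\(s\\) 2")
  expect_error(mortality_rates(-1, 10), "non-negative")
})

test_that("zero mortality until 80 then 1/m gives e(40) = 42 exactly", {
  d <- c(rep(0, 8), 50)
  py <- c(rep(1000, 8), 100) # terminal m = 0.5
  lt <- build_life_table(d, py, SCHEME)
  expect_equal(expectancy_at(lt, 40)$e, 42, tolerance = 1e-12)
  expect_equal(expectancy_at(lt, 80)$e, 2, tolerance = 1e-12)
  expect_true(all(lt$var_q == 0))
  expect_equal(lt$q[9], 1)
  expect_equal(sum(lt$d), lt$l[1], tolerance = 1e-9)
})

test_that("exact constant-rate counts reproduce 1/lambda", {
  # with a = 0.5 the m -> q -> L chain is exactly consistent for constant m,
  # so the 0.5% tolerance of the closed-form comparison is met with margin
  lt <- exact_rate_table(rep(0.05, 9), SCHEME)
  expect_equal(expectancy_at(lt, 40)$e, 20, tolerance = 0.005 * 20)
  expect_equal(expectancy_at(lt, 40)$e, 20, tolerance = 1e-9)
  lt2 <- exact_rate_table(rep(0.1, 9), SCHEME)
  expect_equal(expectancy_at(lt2, 40)$e, 10, tolerance = 1e-9)
})

test_that("when nearly everyone dies in the first band e(40) approaches a*n", {
  # q -> 1 as m -> 0.4 (5-year bands, a = 0.5); survivors past 40-45 are rare
  d <- c(3990, rep(1, 7), 5)
  py <- c(10000, rep(1000, 7), 10)
  lt <- build_life_table(d, py, SCHEME)
  expect_equal(expectancy_at(lt, 40)$e, 2.5, tolerance = 0.02)
  # a closed band that truly exhausts the cohort is rejected
  expect_error(build_life_table(c(5000, rep(1, 7), 5), py, SCHEME),
               "survivorship")
})

test_that("life-table invariants hold on randomized counts", {
  set.seed(303)
  for (rep in 1:20) {
    lam <- runif(9, 0.002, 0.25)
    py <- runif(9, 200, 5000)
    d <- rpois(9, lam * py)
    d[9] <- max(d[9], 1L)
    lt <- build_life_table(d, py, SCHEME)
    expect_true(all(lt$q >= 0 & lt$q <= 1))
    expect_equal(lt$q[9], 1)
    expect_true(all(diff(lt$l) <= 0) && all(lt$l > 0))
    expect_equal(sum(lt$d), lt$l[1], tolerance = 1e-6)
    expect_true(all(diff(lt$T) <= 0))
    expect_true(all(lt$var_q >= 0) && all(lt$se_e >= 0))
    # e_x can exceed e_{x+n} by at most the band width
    expect_true(all(diff(lt$e) > -SCHEME$width[-9] - 1e-9))
    # radix invariance of e and se
    lt2 <- build_life_table(d, py, SCHEME, radix = 1)
    expect_equal(lt2$e, lt$e, tolerance = 1e-9)
    expect_equal(lt2$se_e, lt$se_e, tolerance = 1e-9)
  }
})

test_that("increasing any single band rate never increases any expectancy", {
  set.seed(404)
  py <- runif(9, 500, 2000)
  d <- rpois(9, 0.03 * py) + 1L
  base <- build_life_table(d, py, SCHEME)
  for (j in 1:9) {
    d2 <- d
    d2[j] <- ceiling(d[j] * 1.5) + 2L
    worse <- build_life_table(d2, py, SCHEME)
    expect_true(all(worse$e <= base$e + 1e-12))
  }
})

test_that("terminal band with no deaths is unreportable", {
  expect_error(build_life_table(c(rep(5, 8), 0), rep(1000, 9), SCHEME),
               "terminal")
})

test_that("expectancy_at returns the tabulated row and rejects other ages", {
  lt <- exact_rate_table(rep(0.05, 9), SCHEME)
  est <- expectancy_at(lt, 60)
  expect_equal(est$ci[2] - est$e, 1.96 * est$se, tolerance = 1e-12)
  expect_equal(est$e - est$ci[1], 1.96 * est$se, tolerance = 1e-12)
  expect_error(expectancy_at(lt, 62), "band start")
})

test_that("le_difference subtracts, combines ses, and is antisymmetric", {
  set.seed(99)
  py <- runif(9, 500, 3000)
  t1 <- build_life_table(rpois(9, 0.02 * py) + 1L, py, SCHEME, stratum = "s1")
  t2 <- build_life_table(rpois(9, 0.05 * py) + 1L, py, SCHEME, stratum = "s2")
  d <- le_difference(t1, t2, 50)
  e1 <- expectancy_at(t1, 50); e2 <- expectancy_at(t2, 50)
  expect_equal(d$difference, e1$e - e2$e)
  expect_equal(d$se, sqrt(e1$se^2 + e2$se^2))
  expect_equal(d$ci, d$difference + c(-1, 1) * 1.96 * d$se)
  back <- le_difference(t2, t1, 50)
  expect_equal(back$difference, -d$difference)
  expect_equal(back$se, d$se)

  self <- le_difference(t1, t1, 50)
  expect_identical(self$difference, 0)
  expect_identical(self$ci, c(0, 0))

  other <- age_band_scheme(start_age = 50)
  t3 <- build_life_table(rep(5, other$n_bands), rep(1000, other$n_bands), other)
  expect_error(le_difference(t1, t3, 50), "schemes")
})
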