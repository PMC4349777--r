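test_that("eGFR categories are half-open and exhaustive", {
  expect_equal(categorize_egfr(c(60, 59.999, 45, 44.999, 30, 29.999, 15, 14.9, 0)),
               c("GE60", "C45_59", "C45_59", "C30_44", "C30_44", "C15_29",
                 "C15_29", "EXCLUDED_LT15", "EXCLUDED_LT15"))
  expect_equal(categorize_egfr(120), "GE60")
  expect_error(categorize_egfr(-0.1), "non-negative")
})

test_that("ACR thresholds are inclusive at 30 and 300", {
  expect_equal(categorize_acr(c(0, 29.999, 30, 150, 300, 300.001)),
               c("NORMAL", "NORMAL", "MILD", "MILD", "MILD", "HEAVY"))
  expect_error(categorize_acr(-1), "non-negative")
})

test_that("summarize_albuminuria takes the median and prefers ACR", {
  expect_equal(summarize_albuminuria(c(25, 40, 500)),
               list(category = "MILD", source = "ACR"))
  expect_equal(summarize_albuminuria(numeric(0), c("negative", "trace", "trace")),
               list(category = "MILD", source = "DIPSTICK"))
  # ACR wins even when dipstick says heavy
  expect_equal(summarize_albuminuria(10, c("2+")),
               list(category = "NORMAL", source = "ACR"))
  # even counts: arithmetic midpoint for ACR, lower-middle for dipstick
  expect_equal(summarize_albuminuria(c(20, 40))$category, "MILD") # median 30
  expect_equal(summarize_albuminuria(numeric(0), c("negative", "trace"))$category,
               "NORMAL")
  expect_equal(summarize_albuminuria(numeric(0), c("3+", "2+"))$category, "HEAVY")
  expect_equal(summarize_albuminuria(numeric(0), "1+")$category, "MILD")
  expect_error(summarize_albuminuria(numeric(0), character(0)), "no albuminuria")
  expect_error(summarize_albuminuria(numeric(0), "4+"), "unknown dipstick")
})

test_that("summarize_albuminuria is invariant to permutation of its lists", {
  set.seed(42)
  for (rep in 1:25) {
    acr <- stats::rlnorm(sample(1:6, 1), meanlog = 3.5, sdlog = 1.5)
    base <- summarize_albuminuria(acr)
    expect_identical(summarize_albuminuria(acr[sample.int(length(acr))]), base)
    dip <- sample(c("negative", "trace", "1+", "2+", "3+"),
                  sample(1:6, 1), replace = TRUE)
    base_d <- summarize_albuminuria(numeric(0), dip)
    expect_identical(summarize_albuminuria(numeric(0), dip[sample.int(length(dip))]),
                     base_d)
  }
})

test_that("the KDIGO matrix matches the 2012 guideline and is monotone", {
  expect_equal(kdigo_risk("GE60", "NORMAL"), "LOW")
  expect_equal(kdigo_risk("GE60", "MILD"), "MODERATE")
  expect_equal(kdigo_risk("C45_59", "NORMAL"), "MODERATE")
  expect_equal(kdigo_risk("GE60", "HEAVY"), "HIGH")
  expect_equal(kdigo_risk("C45_59", "MILD"), "HIGH")
  expect_equal(kdigo_risk("C30_44", "NORMAL"), "HIGH")
  expect_equal(kdigo_risk("C45_59", "HEAVY"), "VERY_HIGH")
  expect_equal(kdigo_risk("C30_44", "MILD"), "VERY_HIGH")
  expect_equal(kdigo_risk("C30_44", "HEAVY"), "VERY_HIGH")
  expect_equal(kdigo_risk("C15_29", c("NORMAL", "MILD", "HEAVY")),
               rep("VERY_HIGH", 3))
  expect_error(kdigo_risk("EXCLUDED_LT15", "NORMAL"), "undefined")

  # worsening either axis never lowers the risk rank
  egfr <- c("GE60", "C45_59", "C30_44", "C15_29")
  alb <- c("NORMAL", "MILD", "HEAVY")
  rank <- function(e, a) match(kdigo_risk(e, a), c("LOW", "MODERATE", "HIGH", "VERY_HIGH"))
  for (j in seq_along(alb)) {
    expect_true(all(diff(vapply(egfr, rank, 0L, a = alb[j])) >= 0))
  }
  for (i in seq_along(egfr)) {
    expect_true(all(diff(vapply(alb, rank, 0L, e = egfr[i])) >= 0))
  }
})

test_that("category from creatinine never improves as creatinine rises", {
  scr <- seq(0.4, 8, by = 0.05)
  cat_rank <- match(categorize_egfr(compute_egfr(scr, 65, "female")),
                    c("GE60", "C45_59", "C30_44", "C15_29", "EXCLUDED_LT15"))
  expect_true(all(diff(cat_rank) >= 0))
})

test_that("classify_cohort applies the cohort exclusions with reasons", {
  persons <- rbind(
    make_person("ok", serum_creatinine = 0.9),
    make_person("dial", dialysis = TRUE),
    make_person("lowgfr", serum_creatinine = invert_egfr(10, 50, "male")),
    make_person("noalb", acr = list(numeric(0)), dip = list(character(0)))
  )
  prof <- classify_cohort(persons)
  expect_equal(prof$excluded, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(prof$exclusion_reason,
               c(NA, "dialysis_or_transplant", "egfr_lt15", "no_albuminuria_measure"))
  ok <- prof[1, ]
  expect_equal(ok$egfr_category, "GE60")
  expect_equal(ok$albuminuria_category, "NORMAL")
  expect_equal(ok$albuminuria_source, "ACR")
  expect_equal(ok$kdigo_risk, "LOW")
  expect_true(is.na(prof$kdigo_risk[2]))
  # dialysis flag dominates a low eGFR
  both <- make_person("b", dialysis = TRUE,
                      serum_creatinine = invert_egfr(10, 50, "male"))
  expect_equal(classify_cohort(both)$exclusion_reason, "dialysis_or_transplant")
  expect_error(classify_cohort(persons[, setdiff(names(persons), "sex")]),
               "lacks column")
})
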