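#' @title Kidney-function and albuminuria categorization
#' @name kidney-classify
#' @description Category levels used throughout the package. eGFR categories
#' are half-open and exhaustive: `GE60` = \[60, Inf), `C45_59` = \[45, 60),
#' `C30_44` = \[30, 45), `C15_29` = \[15, 30), `EXCLUDED_LT15` = \[0, 15)
#' (persons below 15 are excluded from the cohort, as are those on dialysis
#' or with a transplant at entry). Albuminuria categories by
#' albumin-to-creatinine ratio (ACR, mg/g): `NORMAL` < 30, `MILD` 30--300
#' inclusive, `HEAVY` > 300; by dipstick: negative -> `NORMAL`, trace or
#' 1+ -> `MILD`, 2+ and above -> `HEAVY`.
NULL

egfr_levels <- c("GE60", "C45_59", "C30_44", "C15_29", "EXCLUDED_LT15")
albuminuria_levels <- c("NORMAL", "MILD", "HEAVY")
kdigo_levels <- c("LOW", "MODERATE", "HIGH", "VERY_HIGH")
dipstick_levels <- c("negative", "trace", "1+", "2+", "3+")

#' Categorize eGFR values
#'
#' @param egfr Numeric vector of eGFR values (mL/min/1.73 m^2), all >= 0.
#' @return Character vector with levels `GE60`, `C45_59`, `C30_44`, `C15_29`,
#'   `EXCLUDED_LT15` (half-open intervals; 60 maps to `GE60`, 59.999 to
#'   `C45_59`).
#' @export
categorize_egfr <- function(egfr) {
  if (any(!is.finite(egfr)) || any(egfr < 0)) stop("eGFR must be non-negative and finite")
  cuts <- c(0, 15, 30, 45, 60, Inf)
  as.character(cut(egfr, breaks = cuts, right = FALSE, labels = rev(egfr_levels)))
}

#' Categorize a single ACR value (mg/g)
#'
#' Boundary values 30 and 300 are `MILD` (the 30--300 range is inclusive).
#'
#' @param acr Numeric vector of ACR values, mg/g.
#' @return Character vector of albuminuria categories.
#' @export
categorize_acr <- function(acr) {
  if (any(!is.finite(acr)) || any(acr < 0)) stop("ACR must be non-negative and finite")
  ifelse(acr < 30, "NORMAL", ifelse(acr <= 300, "MILD", "HEAVY"))
}

dipstick_ordinal <- function(x) {
  i <- match(as.character(x), dipstick_levels)
  if (anyNA(i)) {
    stop("unknown dipstick reading(s): ",
         paste(unique(x[is.na(i)]), collapse = ", "),
         " (expected ", paste(dipstick_levels, collapse = "|"), ")")
  }
  i - 1L
}

# median on the ordinal dipstick scale: lower of the two middle values for
# even counts, since an ordinal category cannot be interpolated.
dipstick_median <- function(ordinals) {
  s <- sort(ordinals)
  s[floor((length(s) + 1) / 2)]
}

#' Baseline albuminuria category from repeated measurements
#'
#' ACR takes precedence: when any ACR value is present the category comes from
#' the median ACR (arithmetic midpoint for even counts) and dipstick readings
#' are ignored. Otherwise the median dipstick reading on the ordinal scale
#' negative < trace < 1+ < 2+ < 3+ (lower-middle for even counts) is mapped
#' to a category. Callers are expected to have restricted both lists to the
#' measurement window around the index creatinine (see [read_persons()]).
#'
#' @param acr_values Numeric vector of ACR measurements (mg/g); may be empty.
#' @param dipstick_values Character vector of dipstick readings
#'   (`negative|trace|1+|2+|3+`); may be empty.
#' @return A list with `category` (`NORMAL`/`MILD`/`HEAVY`) and `source`
#'   (`"ACR"` or `"DIPSTICK"`).
#' @examples
#' summarize_albuminuria(c(25, 40, 500), character(0))   # MILD via ACR
#' summarize_albuminuria(numeric(0), c("negative", "trace", "trace"))
#' @export
summarize_albuminuria <- function(acr_values, dipstick_values = character(0)) {
  acr_values <- acr_values[!is.na(acr_values)]
  dipstick_values <- dipstick_values[!is.na(dipstick_values) & nzchar(dipstick_values)]
  if (length(acr_values) > 0) {
    med <- stats::median(acr_values)
    return(list(category = categorize_acr(med), source = "ACR"))
  }
  if (length(dipstick_values) == 0) {
    stop("no albuminuria measurements: at least one ACR or dipstick value is required")
  }
  med <- dipstick_median(dipstick_ordinal(dipstick_values))
  category <- if (med == 0L) "NORMAL" else if (med <= 2L) "MILD" else "HEAVY"
  list(category = category, source = "DIPSTICK")
}

# KDIGO 2012 prognosis matrix over eGFR category (rows) x albuminuria (cols).
kdigo_matrix <- matrix(
  c("LOW",       "MODERATE",  "HIGH",       # GE60
    "MODERATE",  "HIGH",      "VERY_HIGH",  # C45_59
    "HIGH",      "VERY_HIGH", "VERY_HIGH",  # C30_44
    "VERY_HIGH", "VERY_HIGH", "VERY_HIGH"), # C15_29
  nrow = 4, byrow = TRUE,
  dimnames = list(egfr_levels[1:4], albuminuria_levels)
)

#' KDIGO 2012 risk class from eGFR and albuminuria categories
#'
#' The guideline's prognosis cross-classification: risk never decreases as
#' either the eGFR or the albuminuria category worsens.
#'
#' @param egfr_cat Character vector of eGFR categories (not `EXCLUDED_LT15`).
#' @param alb_cat Character vector of albuminuria categories.
#' @return Character vector with levels `LOW`, `MODERATE`, `HIGH`, `VERY_HIGH`.
#' @examples
#' kdigo_risk("GE60", "NORMAL")   # LOW
#' kdigo_risk("C30_44", "NORMAL") # HIGH
#' @export
kdigo_risk <- function(egfr_cat, alb_cat) {
  if (any(egfr_cat == "EXCLUDED_LT15")) {
    stop("KDIGO risk is undefined for excluded category EXCLUDED_LT15")
  }
  i <- match(egfr_cat, rownames(kdigo_matrix))
  j <- match(alb_cat, colnames(kdigo_matrix))
  if (anyNA(i)) stop("unknown eGFR category: ", paste(unique(egfr_cat[is.na(i)]), collapse = ", "))
  if (anyNA(j)) stop("unknown albuminuria category: ", paste(unique(alb_cat[is.na(j)]), collapse = ", "))
  kdigo_matrix[cbind(i, j)]
}

#' Classify a cohort of persons into kidney profiles
#'
#' Applies the cohort exclusions (dialysis/transplant at entry, baseline eGFR
#' < 15, no albuminuria measurement in window), computes eGFR from the index
#' serum creatinine, and derives the eGFR category, albuminuria category and
#' KDIGO risk class for every non-excluded person.
#'
#' @param persons A person data frame as produced by [sample_cohort()] or
#'   [read_persons()]: columns `id`, `sex`, `index_age`, `serum_creatinine`,
#'   list-columns `acr_values` and `dipstick_values`, flags
#'   `on_dialysis_or_transplant`, `has_diabetes`, `has_hypertension`,
#'   `has_cvd`, and follow-up columns `exit_age`, `died`.
#' @param params CKD-EPI constants, see [ckd_epi_params()].
#' @param black Logical, apply the ethnicity factor (default off).
#' @return A data frame with one row per person: `id`, `egfr_value`,
#'   `egfr_category`, `albuminuria_category`, `albuminuria_source`,
#'   `kdigo_risk`, `excluded`, `exclusion_reason`. Excluded persons carry a
#'   reason (`dialysis_or_transplant`, `egfr_lt15`, `no_albuminuria_measure`)
#'   and `NA` categories where undefined.
#' @export
classify_cohort <- function(persons, params = ckd_epi_params(), black = FALSE) {
  required <- c("id", "sex", "index_age", "serum_creatinine",
                "acr_values", "dipstick_values", "on_dialysis_or_transplant")
  missing_cols <- setdiff(required, names(persons))
  if (length(missing_cols) > 0) {
    stop("person table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(persons)
  egfr <- compute_egfr(persons$serum_creatinine, persons$index_age,
                       persons$sex, params = params, black = black)
  egfr_cat <- categorize_egfr(egfr)

  alb_cat <- rep(NA_character_, n)
  alb_src <- rep(NA_character_, n)
  has_alb <- logical(n)
  for (k in seq_len(n)) {
    acr <- persons$acr_values[[k]]
    dip <- persons$dipstick_values[[k]]
    acr <- acr[!is.na(acr)]
    dip <- dip[!is.na(dip) & nzchar(dip)]
    if (length(acr) == 0 && length(dip) == 0) next
    has_alb[k] <- TRUE
    s <- summarize_albuminuria(acr, dip)
    alb_cat[k] <- s$category
    alb_src[k] <- s$source
  }

  reason <- rep(NA_character_, n)
  reason[!has_alb] <- "no_albuminuria_measure"
  reason[egfr_cat == "EXCLUDED_LT15"] <- "egfr_lt15"
  reason[persons$on_dialysis_or_transplant] <- "dialysis_or_transplant"
  excluded <- !is.na(reason)

  risk <- rep(NA_character_, n)
  ok <- !excluded
  risk[ok] <- kdigo_risk(egfr_cat[ok], alb_cat[ok])

  data.frame(
    id = persons$id,
    egfr_value = egfr,
    egfr_category = egfr_cat,
    albuminuria_category = alb_cat,
    albuminuria_source = alb_src,
    kdigo_risk = risk,
    excluded = excluded,
    exclusion_reason = reason,
    stringsAsFactors = FALSE
  )
}
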