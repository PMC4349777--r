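#' Constants of the 2009 CKD-EPI creatinine equation
#'
#' The equation estimates glomerular filtration rate (mL/min/1.73 m^2) from
#' serum creatinine (mg/dL), age and sex as
#' \deqn{141 \cdot \min(S_{cr}/\kappa, 1)^{\alpha} \cdot \max(S_{cr}/\kappa, 1)^{-1.209}
#'       \cdot 0.993^{age} \cdot 1.018[\mathrm{female}] \cdot 1.159[\mathrm{black}]}
#' with sex-specific knot \eqn{\kappa} (0.7 female, 0.9 male) and low-creatinine
#' exponent \eqn{\alpha} (-0.329 female, -0.411 male). The constants are kept
#' as data so they are inspectable and testable rather than baked into code.
#'
#' @return A list of equation constants.
#' @export
ckd_epi_params <- function() {
  list(
    kappa        = c(female = 0.7, male = 0.9),
    alpha        = c(female = -0.329, male = -0.411),
    slope_exponent = -1.209,
    age_base     = 0.993,
    female_factor = 1.018,
    black_factor = 1.159,
    intercept    = 141
  )
}

normalize_sex <- function(sex) {
  s <- tolower(as.character(sex))
  s[s %in% c("m", "male")] <- "male"
  s[s %in% c("f", "female")] <- "female"
  bad <- !(s %in% c("male", "female"))
  if (any(bad)) stop("sex must be 'male' or 'female', got: ",
                     paste(unique(sex[bad]), collapse = ", "))
  s
}

#' Estimated GFR from serum creatinine (CKD-EPI 2009)
#'
#' Vectorized over `scr`, `age` and `sex`. The black-ethnicity factor of the
#' published equation is available but off by default.
#'
#' @param scr Serum creatinine, mg/dL (use [umol_to_mgdl()] for SI inputs).
#' @param age Age in years; the equation is not validated below 18.
#' @param sex "male" or "female" (also accepts "m"/"f").
#' @param params Equation constants, see [ckd_epi_params()].
#' @param black Logical; apply the 1.159 ethnicity factor (default `FALSE`).
#' @return eGFR in mL/min/1.73 m^2; strictly decreasing in `scr` and `age`.
#' @examples
#' compute_egfr(0.9, 50, "male") # about 99.2
#' @export
compute_egfr <- function(scr, age, sex, params = ckd_epi_params(), black = FALSE) {
  if (any(!is.finite(scr)) || any(scr <= 0)) stop("serum creatinine must be positive")
  if (any(!is.finite(age)) || any(age < 18)) {
    stop("age must be >= 18 years (equation not validated below 18)")
  }
  s <- normalize_sex(sex)
  kappa <- unname(params$kappa[s])
  alpha <- unname(params$alpha[s])
  r <- scr / kappa
  egfr <- params$intercept *
    pmin(r, 1)^alpha *
    pmax(r, 1)^params$slope_exponent *
    params$age_base^age
  egfr <- egfr * ifelse(s == "female", params$female_factor, 1)
  if (isTRUE(black)) egfr <- egfr * params$black_factor
  egfr
}

#' Convert serum creatinine from umol/L to mg/dL
#'
#' @param x Creatinine in micromoles per litre.
#' @return Creatinine in mg/dL (division by 88.4).
#' @export
umol_to_mgdl <- function(x) x / 88.4

#' Serum creatinine yielding a target eGFR
#'
#' Inverts the CKD-EPI equation. Because the equation is a two-piece power law
#' in creatinine, strictly decreasing, the inverse has a closed form: with
#' \eqn{C} the eGFR at the knot \eqn{S_{cr}=\kappa}, targets below \eqn{C}
#' invert through the high-creatinine branch and targets above through the
#' low-creatinine branch.
#'
#' @param target_egfr Desired eGFR in (5, 200) mL/min/1.73 m^2.
#' @param age,sex,params,black As in [compute_egfr()].
#' @return Serum creatinine in mg/dL such that `compute_egfr()` returns
#'   `target_egfr` to floating-point accuracy; errors if the solution falls
#'   outside the physiological range 0.2--20 mg/dL.
#' @examples
#' invert_egfr(99.2, 50, "male") # about 0.9
#' @export
invert_egfr <- function(target_egfr, age, sex, params = ckd_epi_params(), black = FALSE) {
  if (any(!is.finite(target_egfr)) || any(target_egfr <= 5) || any(target_egfr >= 200)) {
    stop("target eGFR must lie in (5, 200)")
  }
  if (any(age < 18)) stop("age must be >= 18 years")
  s <- normalize_sex(sex)
  kappa <- unname(params$kappa[s])
  alpha <- unname(params$alpha[s])
  at_knot <- params$intercept * params$age_base^age *
    ifelse(s == "female", params$female_factor, 1) *
    (if (isTRUE(black)) params$black_factor else 1)
  ratio <- target_egfr / at_knot
  expo <- ifelse(ratio < 1, params$slope_exponent, alpha)
  scr <- kappa * ratio^(1 / expo)
  out_of_range <- scr < 0.2 | scr > 20
  if (any(out_of_range)) {
    stop("no physiological creatinine in [0.2, 20] mg/dL for target eGFR ",
         paste(signif(target_egfr[out_of_range], 4), collapse = ", "))
  }
  scr
}
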