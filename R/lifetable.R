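#' Age-specific mortality rates by the person-year method
#'
#' @param deaths Integer vector of deaths per band, `D_i >= 0`.
#' @param person_years Numeric vector of person-years per band, same length.
#' @return `m_i = D_i / PY_i` per band (deaths per person-year).
#' @export
mortality_rates <- function(deaths, person_years) {
  stopifnot(length(deaths) == length(person_years))
  if (any(deaths < 0) || any(person_years < 0)) stop("counts must be non-negative")
  empty <- which(person_years == 0)
  if (length(empty) > 0) {
    stop("no person-years in band(s) ", paste(empty, collapse = ", "),
         ": stratum too sparse for a life table")
  }
  deaths / person_years
}

#' Chiang abridged life table with variances and confidence intervals
#'
#' Builds the abridged life table from per-band deaths and person-years.
#' Closed bands convert the central death rate to a conditional probability of
#' dying via
#' \deqn{q_i = \frac{n_i m_i}{1 + n_i (1 - a_i) m_i}}
#' with \eqn{a_i} the assumed fraction of the band lived by those who die in
#' it (0.5 by default for 5-year adult bands); the open terminal band has
#' \eqn{q_w = 1} and person-years \eqn{L_w = l_w / m_w}. Life expectancy is
#' \eqn{e_i = T_i / l_i} with \eqn{T_i = \sum_{j \ge i} L_j}.
#'
#' Sampling variances follow Chiang's method,
#' \eqn{\widehat{Var}(q_i) = q_i^2 (1-q_i)/D_i} (0 where \eqn{D_i = 0}), with
#' \deqn{Var(e_x) = \frac{\sum_{j=x}^{w-1} l_j^2\,[(1-a_j) n_j + e_{j+1}]^2\,
#'   \widehat{Var}(q_j) + l_w^2 / (m_w^2 D_w)}{l_x^2}.}
#' The terminal term is a delta-method variance for \eqn{e_w = 1/m_w} under
#' Poisson deaths (a Silcocks-style correction for the open interval, which
#' Chiang's original derivation omits); it requires at least one death in the
#' terminal band. Confidence intervals are normal-approximation
#' \eqn{e \pm 1.96\,se}.
#'
#' @param deaths,person_years Per-band counts, ordered as the scheme's bands.
#' @param scheme An [age_band_scheme()]; its band count must match.
#' @param radix Notional starting cohort size `l` at the first age
#'   (default 100,000). Expectancies and their variances do not depend on it.
#' @param a Fraction of band lived by decedents, recycled across closed bands.
#' @param stratum Optional stratum label carried into the result.
#' @return An object of class `life_table`: a data frame with one row per
#'   band and columns `x`, `n`, `a`, `D`, `PY`, `m`, `q`, `l`, `d`, `L`, `T`,
#'   `e`, `var_q`, `se_e`, `ci_lo`, `ci_hi`.
#' @examples
#' sch <- age_band_scheme()
#' py <- rep(1000, sch$n_bands)
#' d <- round(0.05 * py)
#' lt <- build_life_table(d, py, sch)
#' expectancy_at(lt, 40)
#' @export
build_life_table <- function(deaths, person_years, scheme = age_band_scheme(),
                             radix = 1e5, a = 0.5, stratum = NA_character_) {
  nb <- scheme$n_bands
  stopifnot(length(deaths) == nb, length(person_years) == nb)
  if (radix <= 0) stop("radix must be positive")
  m <- mortality_rates(deaths, person_years)
  if (m[nb] <= 0) stop("terminal band has no deaths: expectancy there (1/m) is undefined")
  n <- scheme$width
  a <- rep_len(a, nb)
  if (any(a < 0 | a > 1)) stop("a must lie in [0, 1]")

  q <- n * m / (1 + n * (1 - a) * m)
  q[nb] <- 1
  q <- pmin(q, 1)

  l <- numeric(nb)
  l[1] <- radix
  for (i in seq_len(nb - 1)) l[i + 1] <- l[i] * (1 - q[i])
  if (any(l <= 0)) stop("survivorship reached zero before the terminal band (q = 1 in a closed band)")
  d <- l * q
  L <- n * (c(l[-1], 0) + a * d)
  L[nb] <- l[nb] / m[nb]
  T <- rev(cumsum(rev(L)))
  e <- T / l

  var_q <- ifelse(deaths > 0, q^2 * (1 - q) / deaths, 0)
  var_q[nb] <- 0 # terminal q is 1 by construction; its uncertainty enters via 1/m
  # cumulative variance of e at each band start
  term <- l^2 * ((1 - a) * n + c(e[-1], 0))^2 * var_q
  term[nb] <- l[nb]^2 / (m[nb]^2 * deaths[nb])
  var_e <- rev(cumsum(rev(term))) / l^2
  se_e <- sqrt(var_e)

  z <- 1.96
  out <- data.frame(
    x = scheme$start, n = n, a = a, D = deaths, PY = person_years,
    m = m, q = q, l = l, d = d, L = L, T = T, e = e,
    var_q = var_q, se_e = se_e,
    ci_lo = e - z * se_e, ci_hi = e + z * se_e
  )
  structure(out, scheme = scheme, radix = radix, stratum = stratum,
            conf_level = 0.95,
            class = c("life_table", "data.frame"))
}

#' @export
print.life_table <- function(x, digits = 3, ...) {
  st <- attr(x, "stratum")
  if (!is.na(st)) cat("Chiang abridged life table -- stratum:", st, "\n")
  lab <- attr(x, "scheme")$labels
  show <- data.frame(band = lab,
                     round(as.data.frame(x)[c("D", "PY", "m", "q", "l", "e", "se_e")], digits))
  print(show, row.names = FALSE)
  invisible(x)
}

#' Life expectancy (with CI) at a tabulated index age
#'
#' @param table A [build_life_table()] result.
#' @param index_age A band start of the table's scheme; no interpolation is
#'   performed.
#' @return A list with `e`, `se`, `ci` (length-2 vector).
#' @export
expectancy_at <- function(table, index_age) {
  i <- match(index_age, table$x)
  if (is.na(i)) {
    stop("index_age ", index_age, " is not a band start (available: ",
         paste(table$x, collapse = ", "), ")")
  }
  list(e = table$e[i], se = table$se_e[i], ci = c(table$ci_lo[i], table$ci_hi[i]))
}

#' Difference in life expectancy between two independent strata
#'
#' `difference = e_ref - e_cmp` at the given index age, with standard error
#' `sqrt(se_ref^2 + se_cmp^2)` (independent strata) and a normal 95% CI.
#'
#' @param t_ref,t_cmp Life tables sharing the same age-band scheme.
#' @param index_age A band start.
#' @return An object of class `le_difference`: list with `reference`,
#'   `comparison`, `index_age`, `difference`, `se`, `ci`.
#' @export
le_difference <- function(t_ref, t_cmp, index_age) {
  if (!same_scheme(attr(t_ref, "scheme"), attr(t_cmp, "scheme"))) {
    stop("life tables use different age-band schemes")
  }
  a <- expectancy_at(t_ref, index_age)
  b <- expectancy_at(t_cmp, index_age)
  diff <- a$e - b$e
  # a stratum compared with itself is fully correlated, not independent
  se <- if (identical(as.data.frame(t_ref), as.data.frame(t_cmp))) 0 else sqrt(a$se^2 + b$se^2)
  structure(
    list(reference = attr(t_ref, "stratum"), comparison = attr(t_cmp, "stratum"),
         index_age = index_age, difference = diff, se = se,
         ci = c(diff - 1.96 * se, diff + 1.96 * se)),
    class = "le_difference"
  )
}

#' @export
print.le_difference <- function(x, ...) {
  cat(sprintf("LE difference at age %g: %.2f years (95%% CI %.2f to %.2f)\n",
              x$index_age, x$difference, x$ci[1], x$ci[2]))
  invisible(x)
}
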