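#' Five-year age-band scheme with an open terminal band
#'
#' Defines the abridged life-table age axis: closed bands of fixed width from
#' `start_age` up to `open_band_start`, then a single open-ended terminal band.
#' The default — bands of 5 years from age 40 with an open 80+ band — is the
#' scheme used throughout the package for exposure splitting and life tables.
#'
#' @param start_age First tabulated age (years). Exposure before this age is
#'   left-truncated and contributes nothing.
#' @param band_width Width of the closed bands (years).
#' @param open_band_start Lower bound of the open terminal band (years); must
#'   be `start_age` plus a whole number of band widths.
#' @return An object of class `age_band_scheme`: a list with `start` (band
#'   lower bounds), `width` (band widths, `Inf` for the terminal band),
#'   `labels`, and `n_bands`.
#' @examples
#' sch <- age_band_scheme()
#' sch$labels
#' @export
age_band_scheme <- function(start_age = 40, band_width = 5, open_band_start = 80) {
  stopifnot(is.numeric(start_age), is.numeric(band_width), is.numeric(open_band_start),
            band_width > 0, open_band_start > start_age)
  n_closed <- (open_band_start - start_age) / band_width
  if (abs(n_closed - round(n_closed)) > 1e-9) {
    stop("open_band_start must be start_age plus a whole number of band widths")
  }
  n_closed <- as.integer(round(n_closed))
  starts <- c(start_age + band_width * seq_len(n_closed) - band_width, open_band_start)
  widths <- c(rep(band_width, n_closed), Inf)
  labels <- c(sprintf("%g-%g", starts[-length(starts)], starts[-1]),
              sprintf("%g+", open_band_start))
  structure(
    list(start = starts, width = widths, labels = labels,
         n_bands = n_closed + 1L),
    class = "age_band_scheme"
  )
}

#' @export
print.age_band_scheme <- function(x, ...) {
  cat("Age-band scheme:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
format.age_band_scheme <- function(x, ...) paste(x$labels, collapse = ",")

is_age_band_scheme <- function(x) inherits(x, "age_band_scheme")

same_scheme <- function(a, b) {
  is_age_band_scheme(a) && is_age_band_scheme(b) &&
    length(a$start) == length(b$start) &&
    all(a$start == b$start) && all(a$width == b$width)
}

# band index containing a given (vector of) age(s); NA below the first band.
band_index <- function(age, scheme) {
  idx <- findInterval(age, scheme$start)
  idx[idx == 0L] <- NA_integer_
  idx
}
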