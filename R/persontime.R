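#' Split one follow-up interval into age-band exposure
#'
#' Allocates the follow-up `[entry_age, exit_age)` of a person across the
#' bands of an [age_band_scheme()], left-truncating at the scheme's first age.
#' A death is assigned to the band containing `exit_age` under the half-open
#' convention, so death at an exact band boundary falls in the higher band.
#' Exposure and deaths before the scheme's first age contribute nothing.
#'
#' @param entry_age,exit_age Continuous ages in years, `exit_age >= entry_age`.
#' @param died Logical: did follow-up end in death?
#' @param scheme An [age_band_scheme()].
#' @return A data frame with one row per band: `band_start`, `band_width`,
#'   `person_years`, `death` (0/1).
#' @examples
#' split_exposure(43, 47.5, TRUE, age_band_scheme())
#' @export
split_exposure <- function(entry_age, exit_age, died, scheme = age_band_scheme()) {
  stopifnot(length(entry_age) == 1, length(exit_age) == 1, length(died) == 1)
  m <- split_exposure_matrix(entry_age, exit_age, died, scheme)
  data.frame(
    band_start = scheme$start,
    band_width = scheme$width,
    person_years = as.numeric(m$py[1, ]),
    death = as.integer(m$death[1, ])
  )
}

# Vectorized core: n persons x n_bands matrices of person-years and deaths.
split_exposure_matrix <- function(entry_age, exit_age, died, scheme) {
  if (any(exit_age < entry_age)) stop("exit_age must be >= entry_age")
  n <- length(entry_age)
  nb <- scheme$n_bands
  lo <- scheme$start
  hi <- c(scheme$start[-1], Inf)
  entry <- pmax(entry_age, scheme$start[1])
  # overlap of [entry, exit) with each band [lo_j, hi_j)
  py <- matrix(0, n, nb)
  for (j in seq_len(nb)) {
    py[, j] <- pmax(0, pmin(exit_age, hi[j]) - pmax(entry, lo[j]))
  }
  death <- matrix(0L, n, nb)
  db <- band_index(exit_age, scheme)
  place <- which(as.logical(died) & !is.na(db))
  if (length(place) > 0) death[cbind(place, db[place])] <- 1L
  list(py = py, death = death)
}

#' Aggregate deaths and person-years per stratum, sex and age band
#'
#' Joins persons to their kidney profiles, drops excluded persons, and sums
#' [split_exposure()] contributions within each sex x grouping cell.
#' Grouping is either the full eGFR x albuminuria cross-classification or the
#' four KDIGO risk classes. Total person-years and deaths are conserved: they
#' equal the sums of the individual post-truncation contributions.
#'
#' @param persons Person data frame (see [classify_cohort()]).
#' @param profiles Output of [classify_cohort()] for the same persons.
#' @param grouping `"egfr_x_albuminuria"` or `"kdigo"`.
#' @param scheme An [age_band_scheme()].
#' @return A data frame of class `stratum_counts` with columns `stratum`
#'   (sex/cell key), `sex`, `cell`, `band_start`, `band_width`, `deaths`,
#'   `person_years`; the scheme is attached as attribute `scheme`.
#' @export
aggregate_counts <- function(persons, profiles,
                             grouping = c("egfr_x_albuminuria", "kdigo"),
                             scheme = age_band_scheme()) {
  grouping <- match.arg(grouping)
  if (!all(persons$id %in% profiles$id)) {
    stop("every person must have a profile; missing: ",
         paste(utils::head(setdiff(persons$id, profiles$id), 5), collapse = ", "))
  }
  prof <- profiles[match(persons$id, profiles$id), ]
  if (any(prof$excluded)) {
    persons <- persons[!prof$excluded, , drop = FALSE]
    prof <- prof[!prof$excluded, , drop = FALSE]
  }
  cell <- if (grouping == "kdigo") {
    prof$kdigo_risk
  } else {
    paste(prof$egfr_category, prof$albuminuria_category, sep = ".")
  }
  sex <- normalize_sex(persons$sex)
  key <- paste(sex, cell, sep = "|")

  m <- split_exposure_matrix(persons$index_age, persons$exit_age,
                             persons$died, scheme)
  py <- rowsum(m$py, key)
  de <- rowsum(m$death, key)
  keys <- rownames(py)
  nb <- scheme$n_bands
  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- data.frame(
    stratum = rep(keys, each = nb),
    sex = rep(vapply(parts, `[`, "", 1L), each = nb),
    cell = rep(vapply(parts, `[`, "", 2L), each = nb),
    band_start = rep(scheme$start, times = length(keys)),
    band_width = rep(scheme$width, times = length(keys)),
    deaths = as.integer(t(de)),
    person_years = as.numeric(t(py)),
    stringsAsFactors = FALSE
  )
  structure(out, scheme = scheme, class = c("stratum_counts", "data.frame"))
}

#' Extract one stratum's deaths and person-years vectors
#'
#' @param counts A `stratum_counts` data frame from [aggregate_counts()].
#' @param stratum The stratum key, e.g. `"male|GE60.NORMAL"`.
#' @return A list with `deaths`, `person_years` (one entry per band) and the
#'   `scheme`.
#' @export
stratum_slice <- function(counts, stratum) {
  rows <- counts$stratum == stratum
  if (!any(rows)) stop("no such stratum: ", stratum)
  sl <- counts[rows, ]
  sl <- sl[order(sl$band_start), ]
  list(deaths = sl$deaths, person_years = sl$person_years,
       scheme = attr(counts, "scheme"))
}
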