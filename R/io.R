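#' Write a person table to CSV
#'
#' One row per person; the repeat-measurement list-columns `acr_values` and
#' `dipstick_values` (and optional day-offset columns) are serialized as
#' semicolon-separated fields, empty when no measurement exists. Dipstick
#' readings are spelled `negative|trace|1+|2+|3+`.
#'
#' @param persons Person data frame (see [sample_cohort()]).
#' @param path Output file path.
#' @export
write_persons <- function(persons, path) {
  df <- persons
  for (col in intersect(c("acr_values", "dipstick_values", "acr_days", "dipstick_days"),
                        names(df))) {
    df[[col]] <- vapply(df[[col]], function(v) paste(v, collapse = ";"), "")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

split_field <- function(x, numeric = TRUE) {
  x <- as.character(x) # single-value fields may come back as numbers
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) {
      if (numeric) numeric(0) else character(0)
    } else {
      v <- strsplit(s, ";", fixed = TRUE)[[1]]
      if (numeric) as.numeric(v) else v
    }
  })
}

#' Read a person table from CSV
#'
#' Inverse of [write_persons()]. Optionally converts creatinine from umol/L
#' and restricts albuminuria measurements to a window around the index
#' creatinine when day offsets are present: measurements whose
#' `acr_days`/`dipstick_days` offset exceeds `window_days` in absolute value
#' are dropped, so persons whose only measurements fall outside the window
#' become ineligible (no albuminuria measure) downstream.
#'
#' @param path CSV file written by [write_persons()] (or hand-built with the
#'   same columns).
#' @param creatinine_units `"mg/dL"` (default) or `"umol/L"`.
#' @param window_days Half-width of the measurement window in days (default
#'   183, i.e. the 6-month periods before and after the index creatinine);
#'   applied only where day-offset columns exist.
#' @return A person data frame with list-columns restored.
#' @export
read_persons <- function(path, creatinine_units = c("mg/dL", "umol/L"),
                         window_days = 183) {
  creatinine_units <- match.arg(creatinine_units)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$acr_values <- split_field(df$acr_values, numeric = TRUE)
  df$dipstick_values <- split_field(df$dipstick_values, numeric = FALSE)
  has_acr_days <- "acr_days" %in% names(df)
  has_dip_days <- "dipstick_days" %in% names(df)
  if (has_acr_days) df$acr_days <- split_field(df$acr_days, numeric = TRUE)
  if (has_dip_days) df$dipstick_days <- split_field(df$dipstick_days, numeric = TRUE)
  for (i in seq_len(nrow(df))) {
    if (has_acr_days && length(df$acr_days[[i]]) == length(df$acr_values[[i]]) &&
        length(df$acr_values[[i]]) > 0) {
      keep <- abs(df$acr_days[[i]]) <= window_days
      df$acr_values[[i]] <- df$acr_values[[i]][keep]
      df$acr_days[[i]] <- df$acr_days[[i]][keep]
    }
    if (has_dip_days && length(df$dipstick_days[[i]]) == length(df$dipstick_values[[i]]) &&
        length(df$dipstick_values[[i]]) > 0) {
      keep <- abs(df$dipstick_days[[i]]) <= window_days
      df$dipstick_values[[i]] <- df$dipstick_values[[i]][keep]
      df$dipstick_days[[i]] <- df$dipstick_days[[i]][keep]
    }
  }
  if (creatinine_units == "umol/L") {
    df$serum_creatinine <- umol_to_mgdl(df$serum_creatinine)
  }
  if (!"on_dialysis_or_transplant" %in% names(df)) df$on_dialysis_or_transplant <- FALSE
  df$died <- as.logical(df$died)
  df
}

#' Write stratum counts to CSV
#'
#' Columns: `stratum`, `sex`, `cell`, `band_start`, `band_width`, `deaths`,
#' `person_years`; `band_width` is `Inf` for the open terminal band.
#'
#' @param counts A `stratum_counts` data frame from [aggregate_counts()].
#' @param path Output file path.
#' @export
write_counts <- function(counts, path) {
  utils::write.csv(as.data.frame(counts), path, row.names = FALSE)
  invisible(path)
}

#' Read stratum counts from CSV
#'
#' @param path CSV written by [write_counts()].
#' @param scheme The [age_band_scheme()] the bands refer to; validated against
#'   the band starts in the file.
#' @return A `stratum_counts` data frame.
#' @export
read_counts <- function(path, scheme = age_band_scheme()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stratum", "sex", "cell", "band_start", "band_width", "deaths", "person_years")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) stop("counts file lacks: ", paste(missing_cols, collapse = ", "))
  starts <- sort(unique(as.numeric(df$band_start)))
  if (length(starts) != length(scheme$start) || any(starts != scheme$start)) {
    stop("band starts in file do not match the age-band scheme")
  }
  structure(df, scheme = scheme, class = c("stratum_counts", "data.frame"))
}

#' Read an analysis or simulation configuration from JSON
#'
#' @param path JSON file of key-value pairs; see [cohort_config()] and
#'   [run_analysis()] for recognized keys.
#' @return A named list.
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
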