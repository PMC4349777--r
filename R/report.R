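#' Run the full life-expectancy analysis pipeline
#'
#' Classifies persons, applies the optional sensitivity subset (excluding
#' anyone with diabetes, hypertension or cardiovascular disease), accumulates
#' deaths and person-years per sex x stratum x age band, builds a Chiang life
#' table per stratum, and derives expectancy and difference tables. Strata
#' that fail the life-table preconditions (an empty band, or no deaths in the
#' open terminal band) are reported as insufficient data and skipped with a
#' logged reason rather than silently dropped.
#'
#' @param persons Person data frame from [sample_cohort()] or [read_persons()].
#' @param grouping `"egfr_x_albuminuria"` (difference tables use the
#'   no-albuminuria cell as the reference within each eGFR category) or
#'   `"kdigo"` (losses are referenced to the `LOW` class).
#' @param sexes Which sexes to tabulate.
#' @param index_ages Index ages to report; must be band starts.
#' @param sensitivity Logical; restrict to persons free of diabetes,
#'   hypertension and cardiovascular disease.
#' @param scheme An [age_band_scheme()].
#' @param radix Life-table radix.
#' @param out_dir Optional directory; when given, expectancy/difference/counts
#'   CSVs and a JSON run manifest are written there.
#' @param label Run label recorded in the manifest.
#' @return A list with `grouping`, `counts`, `life_tables` (named by
#'   stratum), `expectancy` (long data frame), `differences` (long data
#'   frame), `skipped` (stratum/reason), and `manifest`.
#' @export
run_analysis <- function(persons,
                         grouping = c("egfr_x_albuminuria", "kdigo"),
                         sexes = c("male", "female"),
                         index_ages = NULL,
                         sensitivity = FALSE,
                         scheme = age_band_scheme(),
                         radix = 1e5,
                         out_dir = NULL,
                         label = "nephrospan") {
  grouping <- match.arg(grouping)
  if (is.null(index_ages)) index_ages <- scheme$start
  if (!all(index_ages %in% scheme$start)) {
    stop("index_ages must be a subset of the band starts: ",
         paste(scheme$start, collapse = ", "))
  }

  n_input <- nrow(persons)
  profiles <- classify_cohort(persons)
  excl_tab <- table(profiles$exclusion_reason[profiles$excluded])

  keep <- !profiles$excluded
  persons_inc <- persons[keep, , drop = FALSE]
  profiles_inc <- profiles[keep, , drop = FALSE]

  n_sensitivity_dropped <- 0L
  if (isTRUE(sensitivity)) {
    free <- !(persons_inc$has_diabetes | persons_inc$has_hypertension | persons_inc$has_cvd)
    n_sensitivity_dropped <- sum(!free)
    persons_inc <- persons_inc[free, , drop = FALSE]
    profiles_inc <- profiles_inc[free, , drop = FALSE]
  }
  sexes <- normalize_sex(sexes)
  in_sex <- normalize_sex(persons_inc$sex) %in% sexes
  persons_inc <- persons_inc[in_sex, , drop = FALSE]
  profiles_inc <- profiles_inc[in_sex, , drop = FALSE]

  pre40 <- persons_inc$exit_age <= scheme$start[1]
  counts <- aggregate_counts(persons_inc, profiles_inc, grouping, scheme)

  tables <- list()
  skipped <- data.frame(stratum = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (key in unique(counts$stratum)) {
    sl <- stratum_slice(counts, key)
    tb <- tryCatch(
      build_life_table(sl$deaths, sl$person_years, scheme,
                       radix = radix, stratum = key),
      error = function(e) conditionMessage(e)
    )
    if (is.character(tb)) {
      message("skipping stratum ", key, ": ", tb)
      skipped <- rbind(skipped, data.frame(stratum = key, reason = tb,
                                           stringsAsFactors = FALSE))
    } else {
      tables[[key]] <- tb
    }
  }

  expectancy <- expectancy_frame(tables, index_ages)
  differences <- difference_frame(tables, index_ages, grouping)

  manifest <- list(
    label = label,
    grouping = grouping,
    sexes = sexes,
    sensitivity = sensitivity,
    radix = radix,
    scheme = format(scheme),
    n_input = n_input,
    n_excluded = as.list(excl_tab),
    n_sensitivity_dropped = n_sensitivity_dropped,
    n_included = nrow(persons_inc),
    n_followup_entirely_pre_truncation = sum(pre40),
    n_strata_tabulated = length(tables),
    n_strata_skipped = nrow(skipped),
    deaths_total = sum(counts$deaths),
    person_years_total = sum(counts$person_years)
  )

  res <- list(grouping = grouping, counts = counts, life_tables = tables,
              expectancy = expectancy, differences = differences,
              skipped = skipped, manifest = manifest)
  if (!is.null(out_dir)) write_report_bundle(res, out_dir)
  res
}

expectancy_frame <- function(tables, index_ages) {
  rows <- list()
  for (key in names(tables)) {
    tb <- tables[[key]]
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    for (age in index_ages) {
      est <- expectancy_at(tb, age)
      rows[[length(rows) + 1L]] <- data.frame(
        sex = parts[1], cell = parts[2], index_age = age,
        e = est$e, se = est$se, ci_lo = est$ci[1], ci_hi = est$ci[2],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(sex = character(0), cell = character(0),
                      index_age = numeric(0), e = numeric(0), se = numeric(0),
                      ci_lo = numeric(0), ci_hi = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$sex, out$cell, out$index_age), ]
}

empty_difference_frame <- function() {
  data.frame(sex = character(0), reference = character(0),
             comparison = character(0), index_age = numeric(0),
             difference = numeric(0), se = numeric(0),
             ci_lo = numeric(0), ci_hi = numeric(0))
}

difference_frame <- function(tables, index_ages, grouping) {
  if (length(tables) == 0) return(empty_difference_frame())
  rows <- list()
  keys <- names(tables)
  parts <- strsplit(keys, "|", fixed = TRUE)
  sex_of <- vapply(parts, `[`, "", 1L)
  cell_of <- vapply(parts, `[`, "", 2L)
  for (sex in unique(sex_of)) {
    if (grouping == "kdigo") {
      ref_key <- keys[sex_of == sex & cell_of == "LOW"]
      if (length(ref_key) == 0) next
      cmp_keys <- keys[sex_of == sex]
      for (ck in cmp_keys) {
        for (age in index_ages) {
          d <- le_difference(tables[[ref_key]], tables[[ck]], age)
          rows[[length(rows) + 1L]] <- data.frame(
            sex = sex, reference = "LOW", comparison = cell_of[keys == ck],
            index_age = age, difference = d$difference, se = d$se,
            ci_lo = d$ci[1], ci_hi = d$ci[2], stringsAsFactors = FALSE
          )
        }
      }
    } else {
      egfr_of <- vapply(strsplit(cell_of, ".", fixed = TRUE), `[`, "", 1L)
      alb_of <- vapply(strsplit(cell_of, ".", fixed = TRUE), `[`, "", 2L)
      for (eg in unique(egfr_of[sex_of == sex])) {
        ref_key <- keys[sex_of == sex & egfr_of == eg & alb_of == "NORMAL"]
        if (length(ref_key) == 0) next
        for (alb in c("MILD", "HEAVY")) {
          ck <- keys[sex_of == sex & egfr_of == eg & alb_of == alb]
          if (length(ck) == 0) next
          for (age in index_ages) {
            d <- le_difference(tables[[ref_key]], tables[[ck]], age)
            rows[[length(rows) + 1L]] <- data.frame(
              sex = sex, reference = paste0(eg, ".NORMAL"),
              comparison = paste0(eg, ".", alb),
              index_age = age, difference = d$difference, se = d$se,
              ci_lo = d$ci[1], ci_hi = d$ci[2], stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  if (length(rows) == 0) return(empty_difference_frame())
  out <- do.call(rbind, rows)
  out[order(out$sex, out$reference, out$comparison, out$index_age), ]
}

#' Life-expectancy losses referenced to the lowest-risk class
#'
#' Given one sex's life tables keyed by KDIGO risk class, computes
#' `loss(class, age) = e(LOW, age) - e(class, age)` with a CI from
#' [le_difference()]; the loss for `LOW` itself is exactly 0 with CI [0, 0].
#'
#' @param tables Named list of life tables; names are risk classes and must
#'   include `"LOW"`.
#' @param index_ages Band-start ages to report.
#' @return Long data frame: `class`, `index_age`, `e`, `loss`, `se`,
#'   `ci_lo`, `ci_hi`.
#' @export
loss_matrix <- function(tables, index_ages) {
  if (!"LOW" %in% names(tables)) stop("reference class LOW is missing")
  rows <- list()
  for (cls in names(tables)) {
    for (age in index_ages) {
      d <- le_difference(tables[["LOW"]], tables[[cls]], age)
      est <- expectancy_at(tables[[cls]], age)
      rows[[length(rows) + 1L]] <- data.frame(
        class = cls, index_age = age, e = est$e,
        loss = d$difference, se = d$se, ci_lo = d$ci[1], ci_hi = d$ci[2],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out[order(match(out$class, kdigo_levels), out$index_age), ]
}

write_report_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(res$counts, file.path(out_dir, "counts.csv"))
  utils::write.csv(res$expectancy, file.path(out_dir, "expectancy.csv"),
                   row.names = FALSE)
  utils::write.csv(res$differences, file.path(out_dir, "differences.csv"),
                   row.names = FALSE)
  for (sex in unique(res$expectancy$sex)) {
    wide <- expectancy_wide(res$expectancy[res$expectancy$sex == sex, ])
    utils::write.csv(wide, file.path(out_dir, paste0("expectancy_", sex, ".csv")),
                     row.names = FALSE)
  }
  if (nrow(res$skipped) > 0) {
    utils::write.csv(res$skipped, file.path(out_dir, "skipped_strata.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

# rows = index ages, one formatted "e (lo to hi)" column per stratum cell
expectancy_wide <- function(long) {
  ages <- sort(unique(long$index_age))
  cells <- sort(unique(long$cell))
  out <- data.frame(index_age = ages)
  for (cl in cells) {
    sub <- long[long$cell == cl, ]
    out[[cl]] <- vapply(ages, function(a) {
      r <- sub[sub$index_age == a, ]
      if (nrow(r) == 0) return(NA_character_)
      sprintf("%.1f (%.1f to %.1f)", r$e, r$ci_lo, r$ci_hi)
    }, "")
  }
  out
}
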