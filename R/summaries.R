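join_persons <- function(records, persons) {
  idx <- match(records$person_id, persons$person_id)
  if (anyNA(idx)) stop("records contain person_ids absent from the person table")
  dplyr::bind_cols(records,
                   persons[idx, c("sex", "birth_date"), drop = FALSE])
}

#' Per-individual entry statistics
#'
#' Mean, sample standard deviation (n-1), minimum and maximum of the number
#' of entries per individual, overall or grouped. Individuals are those
#' appearing in the records. A group holding a single individual reports
#' `NA` for the SD.
#'
#' @param records Cleaned visit tibble.
#' @param persons Person tibble.
#' @param group_by `NULL` (overall), `"sex"`, or `"birth_year"`.
#' @return A tibble with `n_individuals`, `mean_entries`, `sd_entries`,
#'   `min_entries`, `max_entries` per group.
#' @export
#' @examples
#' # three persons with 2, 4 and 6 entries give mean 4, SD 2
entry_statistics <- function(records, persons, group_by = NULL) {
  stopifnot(is.null(group_by) || group_by %in% c("sex", "birth_year"))
  x <- join_persons(records, persons)
  x$birth_year <- as.integer(format(x$birth_date, "%Y"))
  per_person <- dplyr::summarise(
    dplyr::group_by(x, .data$person_id, .data$sex, .data$birth_year),
    n_entries = dplyr::n(), .groups = "drop")
  g <- if (is.null(group_by)) dplyr::group_by(per_person)
       else dplyr::group_by(per_person, !!rlang::sym(group_by))
  dplyr::summarise(g,
    n_individuals = dplyr::n(),
    mean_entries = mean(.data$n_entries),
    sd_entries = if (dplyr::n() > 1L) stats::sd(.data$n_entries) else NA_real_,
    min_entries = min(.data$n_entries),
    max_entries = max(.data$n_entries),
    .groups = "drop")
}

AGE_PERIODS <- list(`0-6` = 0:6, `7-11` = 7:11, `12-14` = 12:14, `15-18` = 15:18)

age_period <- function(age) {
  cut(age, breaks = c(-1, 6, 11, 14, 18), labels = names(AGE_PERIODS))
}

#' Coverage across the four age periods of eligibility
#'
#' For each individual, counts in how many of the age periods 0-6, 7-11,
#' 12-14 and 15-18 they have at least one entry, then tabulates the
#' distribution over 1-4 periods by sex and in total. Proportions sum to 1
#' within each column.
#'
#' @param records Cleaned visit tibble.
#' @param persons Person tibble.
#' @param rounding Integer-age rule, see [age_at_visit()].
#' @return A tibble with one row per periods-covered value (1-4) and
#'   count/proportion columns per sex and total.
#' @export
period_coverage <- function(records, persons, rounding = c("round", "floor")) {
  rounding <- match.arg(rounding)
  x <- join_persons(records, persons)
  x$age <- age_at_visit(x$visit_date, x$birth_date, rounding)
  x$period <- age_period(x$age)
  per_person <- dplyr::summarise(
    dplyr::group_by(x, .data$person_id, .data$sex),
    n_periods = dplyr::n_distinct(.data$period), .groups = "drop")
  tab <- function(df) {
    tt <- table(factor(df$n_periods, levels = 1:4))
    tibble::tibble(n_periods = 1:4, n = as.integer(tt),
                   proportion = as.integer(tt) / max(1L, sum(tt)))
  }
  total <- tab(per_person)
  f <- tab(per_person[per_person$sex == "F", ])
  m <- tab(per_person[per_person$sex == "M", ])
  tibble::tibble(
    n_periods = 1:4,
    n_female = f$n, prop_female = f$proportion,
    n_male = m$n, prop_male = m$proportion,
    n_total = total$n, prop_total = total$proportion
  )
}

#' Prevalence per 1000 individuals by calendar year and sex or age
#'
#' For each stratum (visit year crossed with sex, or with the index ages
#' 5, 9 and 15 chosen to reflect the temporary, mixed and permanent
#' dentition), reports the number of individuals with a visit, the number
#' positive for the disease at a visit in the stratum, and the prevalence
#' per 1000. Caries positivity is a caries experience of at least
#' `caries_threshold` affected surfaces (dmf_s + DMF_S).
#'
#' @param aggregates Harmonized aggregate tibble from [harmonize_visits()].
#' @param persons Person tibble.
#' @param disease `"gingivitis"`, `"periodontitis"` or `"caries"`.
#' @param strata `"sex"` or `"age"`.
#' @param ages Index ages used when `strata = "age"`.
#' @param caries_threshold Minimum dmf_total counting as caries-positive.
#' @param rounding Integer-age rule, see [age_at_visit()].
#' @return A tibble with `year`, the stratum column, `n_at_risk`,
#'   `n_positive`, `prevalence_per_1000`. Empty strata are omitted.
#' @export
prevalence_by <- function(aggregates, persons,
                          disease = c("gingivitis", "periodontitis", "caries"),
                          strata = c("sex", "age"),
                          ages = c(5L, 9L, 15L),
                          caries_threshold = 1L,
                          rounding = c("round", "floor")) {
  disease <- match.arg(disease)
  strata <- match.arg(strata)
  rounding <- match.arg(rounding)
  x <- join_persons(aggregates, persons)
  x$year <- as.integer(format(x$visit_date, "%Y"))
  x$positive <- switch(disease,
    gingivitis = x$gingivitis_flag,
    periodontitis = x$periodontitis_flag,
    caries = x$dmf_total >= caries_threshold)
  if (strata == "age") {
    x$age <- age_at_visit(x$visit_date, x$birth_date, rounding)
    x <- x[x$age %in% ages, , drop = FALSE]
    g <- dplyr::group_by(x, .data$year, .data$age)
  } else {
    g <- dplyr::group_by(x, .data$year, .data$sex)
  }
  out <- dplyr::summarise(g,
    n_at_risk = dplyr::n_distinct(.data$person_id),
    n_positive = dplyr::n_distinct(.data$person_id[.data$positive]),
    .groups = "drop")
  out$prevalence_per_1000 <- 1000 * out$n_positive / out$n_at_risk
  out
}

#' Visit counts per calendar year under either attribution axis
#'
#' `axis = "visit_year"` attributes each record to the calendar year of the
#' examination. `axis = "report_year"` uses the stored administrative report
#' year where present; from 2000 on the report year disappears from the
#' registry, so the visit year serves as its proxy. Both axes distribute
#' the same records, so their totals over all years are equal.
#'
#' @param records Cleaned visit tibble.
#' @param axis `"visit_year"` or `"report_year"`.
#' @return A tibble with `year` and `n_visits`.
#' @export
visits_by_year <- function(records, axis = c("visit_year", "report_year")) {
  axis <- match.arg(axis)
  vy <- as.integer(format(records$visit_date, "%Y"))
  year <- if (axis == "visit_year") vy
          else ifelse(is.na(records$report_year), vy, records$report_year)
  out <- dplyr::count(tibble::tibble(year = year), .data$year, name = "n_visits")
  dplyr::arrange(out, .data$year)
}

#' Compare registry coverage with external population denominators
#'
#' Counts registry individuals per birth year and compares them with a
#' user-supplied denominator table (births plus child naturalizations per
#' birth year), in absolute numbers and percentages, per year and as a
#' total over the requested range.
#'
#' @param persons Person tibble.
#' @param denominators A tibble with columns `birth_year` and `n` covering
#'   every requested birth year; a missing year is an error naming the
#'   year.
#' @param years Optional integer range of birth years to compare (defaults
#'   to the registry's birth-year span).
#' @return A list with `by_year` (tibble: `birth_year`, `n_registry`,
#'   `n_denominator`, `difference`, `pct_difference`; the percentage is
#'   `NA` where the denominator is 0) and `total` (one-row tibble over the
#'   range).
#' @export
compare_population <- function(persons, denominators, years = NULL) {
  stopifnot(all(c("birth_year", "n") %in% names(denominators)))
  by <- as.integer(format(persons$birth_date, "%Y"))
  if (is.null(years)) years <- range(by)
  yrs <- seq(years[1], years[2])
  missing_years <- setdiff(yrs, denominators$birth_year)
  if (length(missing_years) > 0L) {
    stop("denominator table missing birth year(s): ",
         paste(missing_years, collapse = ", "))
  }
  reg <- table(factor(by[by %in% yrs], levels = yrs))
  den <- denominators$n[match(yrs, denominators$birth_year)]
  by_year <- tibble::tibble(
    birth_year = yrs,
    n_registry = as.integer(reg),
    n_denominator = as.integer(den),
    difference = as.integer(reg) - as.integer(den),
    pct_difference = ifelse(den == 0, NA_real_,
                            100 * (as.integer(reg) - den) / den)
  )
  tot_reg <- sum(by_year$n_registry); tot_den <- sum(by_year$n_denominator)
  total <- tibble::tibble(
    n_registry = tot_reg, n_denominator = tot_den,
    difference = tot_reg - tot_den,
    pct_difference = if (tot_den == 0) NA_real_ else 100 * (tot_reg - tot_den) / tot_den
  )
  list(by_year = by_year, total = total)
}

#' Mean entry counts by disease state
#'
#' Compares how often diseased and disease-free individuals appear in the
#' registry. For gingivitis and periodontitis, individuals are grouped as
#' ever versus never flagged across their visits (`grouping = "ever"`), or
#' by the flag of each calendar year (`grouping = "yearly"`). For caries,
#' the per-individual maximum of dmf_total across all visits is grouped
#' into 0-4, 5-9 and >= 10 affected surfaces.
#'
#' @param records Cleaned visit tibble (defines entry counts).
#' @param aggregates Harmonized aggregates for the same records.
#' @param persons Person tibble.
#' @param grouping `"ever"` or `"yearly"`.
#' @return A tibble with `disease`, `state`, (`year` when yearly),
#'   `n_individuals` and `mean_entries`.
#' @export
mean_entries_by_disease_state <- function(records, aggregates, persons,
                                          grouping = c("ever", "yearly")) {
  grouping <- match.arg(grouping)
  entries <- dplyr::count(records, .data$person_id, name = "n_entries")
  caries_group <- function(m) {
    cut(m, breaks = c(-1, 4, 9, Inf), labels = c("0-4", "5-9", ">=10"))
  }
  if (grouping == "ever") {
    per_person <- dplyr::summarise(
      dplyr::group_by(aggregates, .data$person_id),
      gingivitis = any(.data$gingivitis_flag),
      periodontitis = any(.data$periodontitis_flag),
      max_dmf = max(.data$dmf_total),
      .groups = "drop")
    per_person <- dplyr::inner_join(per_person, entries, by = "person_id")
    one <- function(state, disease) {
      dplyr::summarise(
        dplyr::group_by(tibble::tibble(state = as.character(state),
                                       n_entries = per_person$n_entries),
                        .data$state),
        n_individuals = dplyr::n(),
        mean_entries = mean(.data$n_entries), .groups = "drop") |>
        dplyr::mutate(disease = disease, .before = 1)
    }
    dplyr::bind_rows(
      one(ifelse(per_person$gingivitis, "ever", "never"), "gingivitis"),
      one(ifelse(per_person$periodontitis, "ever", "never"), "periodontitis"),
      one(caries_group(per_person$max_dmf), "caries"))
  } else {
    x <- aggregates
    x$year <- as.integer(format(x$visit_date, "%Y"))
    x <- dplyr::inner_join(x, entries, by = "person_id")
    per_py <- dplyr::summarise(
      dplyr::group_by(x, .data$person_id, .data$year),
      gingivitis = any(.data$gingivitis_flag),
      periodontitis = any(.data$periodontitis_flag),
      max_dmf = max(.data$dmf_total),
      n_entries = .data$n_entries[1],
      .groups = "drop")
    one <- function(state, disease) {
      dplyr::summarise(
        dplyr::group_by(tibble::tibble(year = per_py$year,
                                       state = as.character(state),
                                       n_entries = per_py$n_entries),
                        .data$year, .data$state),
        n_individuals = dplyr::n(),
        mean_entries = mean(.data$n_entries), .groups = "drop") |>
        dplyr::mutate(disease = disease, .before = 1)
    }
    dplyr::bind_rows(
      one(ifelse(per_py$gingivitis, "yes", "no"), "gingivitis"),
      one(ifelse(per_py$periodontitis, "yes", "no"), "periodontitis"),
      one(caries_group(per_py$max_dmf), "caries"))
  }
}
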