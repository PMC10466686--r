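#' Age at visit
#'
#' Exact age in years is the day difference between visit and birth divided
#' by 365.25. Integer age (used for the one-entry-per-age restriction)
#' rounds the exact age with the chosen rule: `"round"` rounds half-down
#' (exact half-years round toward the lower age, so a child exactly 7.5
#' years old counts as 7), `"floor"` truncates as conventional in
#' epidemiology. Rounded ages above 18 (possible for exact ages in
#' (18.5, 19), which the eligibility filter keeps) are clamped to 18 so
#' integer ages always lie in 0-18 for eligible visits.
#'
#' @param visit_date,birth_date `Date` vectors.
#' @param rounding `"exact"`, `"round"` (half-down) or `"floor"`.
#' @return Numeric (exact) or integer age in years.
#' @export
#' @examples
#' age_at_visit(as.Date("1999-06-01"), as.Date("1980-01-01"))  # 19.4...
age_at_visit <- function(visit_date, birth_date,
                         rounding = c("exact", "round", "floor")) {
  rounding <- match.arg(rounding)
  x <- as.numeric(as.Date(visit_date) - as.Date(birth_date)) / 365.25
  switch(rounding,
    exact = x,
    round = pmin(as.integer(ceiling(x - 0.5)), 18L),
    floor = pmin(as.integer(floor(x)), 18L)
  )
}

#' Remove exact-duplicate visit rows
#'
#' Rows equal on every field are reduced to their first occurrence.
#'
#' @param records A visit tibble.
#' @return A list with `records` (deduplicated, stable order) and `n_removed`.
#' @export
drop_duplicates <- function(records) {
  dup <- duplicated(records)
  list(records = records[!dup, , drop = FALSE], n_removed = sum(dup))
}

#' Remove faulty visit records
#'
#' Two fault classes are removed: visits dated after the person's death, and
#' visits at ages outside eligibility for care (the exact age must satisfy
#' 0 < age < 19 years; age exactly 0 or exactly 19 is out). A row failing
#' both rules is counted under the death rule. Rows whose `person_id` does
#' not resolve in the person table cannot be checked and are routed to the
#' `rejected` element, never silently dropped.
#'
#' @param records A visit tibble.
#' @param persons A person tibble (see [read_persons()]).
#' @return A list with `records` (kept rows), `n_death_before_visit`,
#'   `n_age_out_of_range`, and `rejected` (unmatched rows).
#' @export
drop_faulty <- function(records, persons) {
  idx <- match(records$person_id, persons$person_id)
  rejected <- records[is.na(idx), , drop = FALSE]
  kept <- records[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  death <- persons$death_date[idx]
  birth <- persons$birth_date[idx]
  bad_death <- !is.na(death) & death < kept$visit_date
  age <- age_at_visit(kept$visit_date, birth)
  bad_age <- !bad_death & !(age > 0 & age < 19)
  list(
    records = kept[!bad_death & !bad_age, , drop = FALSE],
    n_death_before_visit = sum(bad_death),
    n_age_out_of_range = sum(bad_age),
    rejected = rejected
  )
}

#' Restrict to one entry per person per integer age
#'
#' Keeps, for each person and each integer age, only the earliest-dated
#' visit; a same-date tie is broken toward the first row in stable input
#' order. Assumes faulty records have already been removed.
#'
#' @param records A visit tibble.
#' @param persons A person tibble.
#' @param rounding Integer-age rule, see [age_at_visit()].
#' @return A list with `records` (kept rows, stable order) and `n_removed`.
#' @export
restrict_one_per_age <- function(records, persons, rounding = c("round", "floor")) {
  rounding <- match.arg(rounding)
  if (nrow(records) == 0L) return(list(records = records, n_removed = 0L))
  birth <- persons$birth_date[match(records$person_id, persons$person_id)]
  if (anyNA(birth)) stop("person_id not in person table; run drop_faulty first")
  age <- age_at_visit(records$visit_date, birth, rounding)
  ord <- order(records$person_id, age, records$visit_date, seq_len(nrow(records)))
  first <- !duplicated(paste(records$person_id, age)[ord])
  keep_rows <- sort(ord[first])
  list(records = records[keep_rows, , drop = FALSE],
       n_removed = nrow(records) - length(keep_rows))
}

#' Full record-cleaning pipeline
#'
#' Applies, in order: exact-duplicate removal, faulty-record removal
#' (death before visit; age outside 0 < age < 19), and the
#' one-entry-per-age restriction. The order matters for the per-rule counts
#' and is fixed. The pipeline is idempotent: applying it to its own output
#' removes nothing.
#'
#' @param records A visit tibble.
#' @param persons A person tibble.
#' @param rounding Integer-age rule, see [age_at_visit()].
#' @return A list with `records` (cleaned visits), `report` (a
#'   `cleaning_report`), and `rejected` (rows with unresolvable
#'   `person_id`).
#' @export
clean_pipeline <- function(records, persons, rounding = c("round", "floor")) {
  rounding <- match.arg(rounding)
  n_input <- nrow(records)
  entries_per_person <- function(df) {
    if (nrow(df) == 0L) 0L else max(table(df$person_id))
  }
  s1 <- drop_duplicates(records)
  s2 <- drop_faulty(s1$records, persons)
  max_pre <- entries_per_person(s2$records)
  s3 <- restrict_one_per_age(s2$records, persons, rounding)
  report <- cleaning_report(
    n_input = n_input,
    n_duplicates_removed = s1$n_removed,
    n_death_before_visit = s2$n_death_before_visit,
    n_age_out_of_range = s2$n_age_out_of_range,
    n_age_restriction_removed = s3$n_removed,
    n_rejected = nrow(s2$rejected),
    n_output = nrow(s3$records),
    max_entries_pre_restriction = max_pre,
    max_entries_post_restriction = entries_per_person(s3$records)
  )
  list(records = s3$records, report = report, rejected = s2$rejected)
}

#' Auditable cleaning report
#'
#' Counts of rows removed per cleaning rule. Conservation always holds:
#' `n_input = n_output + n_duplicates_removed + n_faulty_removed +
#' n_age_restriction_removed + n_rejected`. Because the source text is
#' ambiguous about whether its reported per-individual entry maximum refers
#' to the data before or after the one-entry-per-age restriction, both
#' maxima are reported.
#'
#' @param n_input,n_duplicates_removed,n_death_before_visit,n_age_out_of_range,n_age_restriction_removed,n_rejected,n_output,max_entries_pre_restriction,max_entries_post_restriction
#'   Integer counts.
#' @return A `cleaning_report` object (a named list); construction fails if
#'   conservation does not hold.
#' @export
cleaning_report <- function(n_input, n_duplicates_removed, n_death_before_visit,
                            n_age_out_of_range, n_age_restriction_removed,
                            n_rejected = 0L, n_output,
                            max_entries_pre_restriction = NA_integer_,
                            max_entries_post_restriction = NA_integer_) {
  n_faulty_removed <- n_death_before_visit + n_age_out_of_range
  x <- list(
    n_input = as.integer(n_input),
    n_duplicates_removed = as.integer(n_duplicates_removed),
    n_faulty_removed = as.integer(n_faulty_removed),
    n_death_before_visit = as.integer(n_death_before_visit),
    n_age_out_of_range = as.integer(n_age_out_of_range),
    n_age_restriction_removed = as.integer(n_age_restriction_removed),
    n_rejected = as.integer(n_rejected),
    n_output = as.integer(n_output),
    max_entries_pre_restriction = as.integer(max_entries_pre_restriction),
    max_entries_post_restriction = as.integer(max_entries_post_restriction)
  )
  if (x$n_input != x$n_output + x$n_duplicates_removed + x$n_faulty_removed +
      x$n_age_restriction_removed + x$n_rejected) {
    stop("cleaning report violates row conservation")
  }
  structure(x, class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cleaning report\n")
  cat(sprintf("  input rows:                %d\n", x$n_input))
  cat(sprintf("  duplicates removed:        %d\n", x$n_duplicates_removed))
  cat(sprintf("  faulty removed:            %d (death-before-visit %d, age-out-of-range %d)\n",
              x$n_faulty_removed, x$n_death_before_visit, x$n_age_out_of_range))
  cat(sprintf("  age-restriction removed:   %d\n", x$n_age_restriction_removed))
  if (x$n_rejected > 0L)
    cat(sprintf("  rejected (unknown person): %d\n", x$n_rejected))
  cat(sprintf("  output rows:               %d\n", x$n_output))
  cat(sprintf("  max entries/person pre/post restriction: %d / %d\n",
              x$max_entries_pre_restriction, x$max_entries_post_restriction))
  invisible(x)
}
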