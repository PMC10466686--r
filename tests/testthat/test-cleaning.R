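test_that("exact duplicates reduce to the first occurrence", {
  v <- make_visit("ERA2")
  three <- dplyr::bind_rows(v, v, v)
  res <- drop_duplicates(three)
  expect_identical(nrow(res$records), 1L)
  expect_identical(res$n_removed, 2L)
  clean <- dplyr::bind_rows(make_visit("ERA2", person_id = "P1"),
                            make_visit("ERA2", person_id = "P2"))
  res2 <- drop_duplicates(clean)
  expect_identical(res2$n_removed, 0L)
  expect_equal(res2$records, clean)
})

test_that("faulty filters: death before visit, exact age outside (0, 19)", {
  persons <- dplyr::bind_rows(
    make_person("PD", birth_date = "1990-01-01", death_date = "2001-01-01"),
    make_person("PA", birth_date = "1980-01-01"))
  v <- dplyr::bind_rows(
    make_visit("ERA3", person_id = "PD", visit_date = "2002-05-05"),  # after death
    make_visit("ERA2", person_id = "PA", visit_date = "1999-06-01"),  # age 19.4
    make_visit("ERA1", person_id = "PA", visit_date = "1980-07-01"),  # age 0.5
    make_visit("ERA2", person_id = "PA", visit_date = "1998-12-01"))  # age 18.9
  res <- drop_faulty(v, persons)
  expect_identical(res$n_death_before_visit, 1L)
  expect_identical(res$n_age_out_of_range, 1L)
  expect_identical(nrow(res$records), 2L)
  # boundary: age exactly 0 and exactly 19 are both out
  v0 <- make_visit("ERA1", person_id = "PA", visit_date = "1980-01-01")
  expect_identical(drop_faulty(v0, persons)$n_age_out_of_range, 1L)
})

test_that("unresolvable person_id is routed to rejected, not dropped", {
  persons <- make_person("P1")
  v <- dplyr::bind_rows(make_visit("ERA2", person_id = "P1"),
                        make_visit("ERA2", person_id = "GHOST"))
  res <- drop_faulty(v, persons)
  expect_identical(nrow(res$rejected), 1L)
  expect_identical(res$rejected$person_id, "GHOST")
  cl <- clean_pipeline(v, persons)
  expect_identical(cl$report$n_rejected, 1L)
  expect_identical(cl$report$n_input,
                   cl$report$n_output + cl$report$n_duplicates_removed +
                     cl$report$n_faulty_removed + cl$report$n_age_restriction_removed +
                     cl$report$n_rejected)
})

test_that("one entry per integer age keeps the earliest, stable on ties", {
  persons <- make_person("P1", birth_date = "1993-01-01")
  v <- dplyr::bind_rows(
    make_visit("ERA3", person_id = "P1", visit_date = "2000-05-01", ging_11 = "1"),
    make_visit("ERA3", person_id = "P1", visit_date = "2000-03-01"))
  res <- restrict_one_per_age(v, persons)  # both round to age 7
  expect_identical(res$n_removed, 1L)
  expect_identical(res$records$visit_date, as.Date("2000-03-01"))
  # same date, same age: first row in input order wins
  tie <- dplyr::bind_rows(
    make_visit("ERA3", person_id = "P1", visit_date = "2000-03-01", ging_11 = "1"),
    make_visit("ERA3", person_id = "P1", visit_date = "2000-03-01", ging_12 = "1"))
  res2 <- restrict_one_per_age(tie, persons)
  expect_identical(res2$n_removed, 1L)
  expect_identical(res2$records$ging_11, "1")
  # one visit per age: unchanged
  one <- make_visit("ERA3", person_id = "P1", visit_date = "2001-03-01")
  expect_identical(restrict_one_per_age(one, persons)$n_removed, 0L)
})

test_that("integer-age rounding rules behave as documented", {
  b <- as.Date("1990-01-01")
  half <- b + round(7.5 * 365.25)
  expect_identical(age_at_visit(half, b, "round"), 7L)   # half rounds down
  expect_identical(age_at_visit(b + round(7.6 * 365.25), b, "round"), 8L)
  expect_identical(age_at_visit(b + round(7.9 * 365.25), b, "floor"), 7L)
  # exact ages in (18.5, 19) clamp into the 18 bucket
  expect_identical(age_at_visit(b + round(18.8 * 365.25), b, "round"), 18L)
})

test_that("the full pipeline is idempotent and conserves rows", {
  cfg <- simulation_config(n_individuals = 60, birth_year_range = c(1970, 2000),
                           duplicate_rate = 0.05, faulty_death_rate = 0.01,
                           faulty_age_rate = 0.01, seed = 21)
  sim <- simulate_cohort(cfg)
  cl <- clean_pipeline(sim$visits, sim$persons)
  r <- cl$report
  expect_identical(r$n_input,
                   r$n_output + r$n_duplicates_removed + r$n_faulty_removed +
                     r$n_age_restriction_removed + r$n_rejected)
  again <- clean_pipeline(cl$records, sim$persons)
  expect_identical(again$report$n_duplicates_removed, 0L)
  expect_identical(again$report$n_faulty_removed, 0L)
  expect_identical(again$report$n_age_restriction_removed, 0L)
  expect_equal(again$records, cl$records)
  # output: at most 19 records per person, distinct integer ages 0..18
  birth <- sim$persons$birth_date[match(cl$records$person_id, sim$persons$person_id)]
  age <- age_at_visit(cl$records$visit_date, birth, "round")
  expect_true(all(age >= 0 & age <= 18))
  expect_false(any(duplicated(paste(cl$records$person_id, age))))
  expect_lte(max(table(cl$records$person_id)), 19L)
})

test_that("cleaning removals match the injected fault ledger exactly", {
  cfg <- simulation_config(n_individuals = 80, birth_year_range = c(1972, 2000),
                           duplicate_rate = 0.04, faulty_death_rate = 0.008,
                           faulty_age_rate = 0.008, seed = 77)
  sim <- simulate_cohort(cfg)
  cl <- clean_pipeline(sim$visits, sim$persons)
  expect_identical(cl$report$n_duplicates_removed, length(sim$ledger$duplicates))
  expect_identical(cl$report$n_death_before_visit, length(sim$ledger$death_before_visit))
  expect_identical(cl$report$n_age_out_of_range, length(sim$ledger$age_out_of_range))
  expect_identical(cl$report$n_age_restriction_removed, 0L)
})
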