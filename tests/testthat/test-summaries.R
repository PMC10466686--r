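three_person_fixture <- function() {
  persons <- make_person(c("P1", "P2", "P3"), c("F", "M", "F"),
                         rep("1990-01-01", 3))
  counts <- c(P1 = 2L, P2 = 4L, P3 = 6L)
  v <- dplyr::bind_rows(lapply(names(counts), function(p) {
    dplyr::bind_rows(lapply(seq_len(counts[[p]]), function(a) {
      make_visit("ERA2", person_id = p,
                 visit_date = as.Date("1990-01-01") + round((a + 2) * 365.25) + 60)
    }))
  }))
  list(persons = persons, visits = v)
}

test_that("entry statistics: mean, sample SD, min, max per individual", {
  fx <- three_person_fixture()
  s <- entry_statistics(fx$visits, fx$persons)
  expect_identical(s$n_individuals, 3L)
  expect_equal(s$mean_entries, 4)
  expect_equal(s$sd_entries, 2)  # sample SD of 2, 4, 6
  expect_identical(c(s$min_entries, s$max_entries), c(2L, 6L))
  # single individual: SD undefined
  one <- entry_statistics(fx$visits[fx$visits$person_id == "P1", ], fx$persons)
  expect_identical(one$n_individuals, 1L)
  expect_true(is.na(one$sd_entries))
  # by sex: only groups present appear
  by_sex <- entry_statistics(fx$visits, fx$persons, "sex")
  expect_setequal(by_sex$sex, c("F", "M"))
  expect_equal(by_sex$mean_entries[by_sex$sex == "M"], 4)
})

test_that("period coverage counts distinct age periods, boundaries included", {
  persons <- make_person(c("A", "B", "C"), c("F", "M", "F"), rep("1990-01-01", 3))
  mk <- function(p, ages) {
    dplyr::bind_rows(lapply(ages, function(a) {
      make_visit("ERA2", person_id = p,
                 visit_date = as.Date("1990-01-01") + round(a * 365.25) + 60)
    }))
  }
  v <- dplyr::bind_rows(mk("A", c(3, 8, 13, 16)),  # 4 periods
                        mk("B", c(3, 4, 5)),       # 1 period
                        mk("C", c(6, 7)))          # 6 in 0-6, 7 in 7-11
  cov <- period_coverage(v, persons)
  expect_identical(cov$n_total[cov$n_periods == 4], 1L)
  expect_identical(cov$n_total[cov$n_periods == 1], 1L)
  expect_identical(cov$n_total[cov$n_periods == 2], 1L)
  expect_equal(sum(cov$prop_total), 1)
  expect_equal(sum(cov$prop_female), 1)
  expect_identical(sum(cov$n_total), 3L)
})

test_that("prevalence per 1000 is positives over individuals at risk", {
  persons <- make_person(sprintf("P%02d", 1:10), rep(c("F", "M"), 5),
                         rep("1980-01-01", 10))
  v <- dplyr::bind_rows(lapply(1:10, function(i) {
    make_visit("ERA2", person_id = sprintf("P%02d", i), visit_date = "1995-06-01",
               ging_11 = if (i <= 2) "2" else NA)
  }))
  # two visits positive via 6 teeth coded 2
  for (t in c(11, 12, 21, 22, 31, 32)) v[[paste0("ging_", t)]][1:2] <- "2"
  agg <- harmonize_visits(v)
  tab <- prevalence_by(agg, persons, "gingivitis", "age", ages = 15L)
  expect_identical(tab$n_at_risk, 10L)
  expect_identical(tab$n_positive, 2L)
  expect_equal(tab$prevalence_per_1000, 200)
  none <- prevalence_by(agg, persons, "periodontitis", "age", ages = 15L)
  expect_equal(none$prevalence_per_1000, 0)
  expect_true(all(tab$prevalence_per_1000 >= 0 & tab$prevalence_per_1000 <= 1000))
})

test_that("visit-year axes attribute records differently but conserve totals", {
  v <- dplyr::bind_rows(
    make_visit("ERA1", visit_date = "1987-10-01", report_year = 1988L),
    make_visit("ERA3", visit_date = "2005-03-03"))
  by_visit <- visits_by_year(v, "visit_year")
  by_report <- visits_by_year(v, "report_year")
  expect_identical(by_visit$n_visits[by_visit$year == 1987], 1L)
  expect_identical(by_report$n_visits[by_report$year == 1988], 1L)
  expect_identical(by_visit$n_visits[by_visit$year == 2005], 1L)
  expect_identical(by_report$n_visits[by_report$year == 2005], 1L)
  expect_identical(sum(by_visit$n_visits), sum(by_report$n_visits))
})

test_that("population comparison reports absolute and percent differences", {
  persons <- make_person(sprintf("P%03d", 1:104), "F",
                         rep("1990-06-01", 104))
  den <- tibble::tibble(birth_year = 1990L, n = 100L)
  cmp <- compare_population(persons, den, years = c(1990, 1990))
  expect_identical(cmp$by_year$difference, 4L)
  expect_equal(cmp$by_year$pct_difference, 4)
  expect_identical(cmp$total$difference, 4L)
  # equal counts give zero difference
  den2 <- tibble::tibble(birth_year = 1990L, n = 104L)
  expect_equal(compare_population(persons, den2, c(1990, 1990))$total$pct_difference, 0)
  # missing denominator year errors naming the year
  expect_error(compare_population(persons, den, years = c(1989, 1990)), "1989")
  # zero denominator: percentage undefined
  den0 <- tibble::tibble(birth_year = 1990L, n = 0L)
  expect_true(is.na(compare_population(persons, den0, c(1990, 1990))$by_year$pct_difference))
})

test_that("disease-state grouping uses ever/never flags and max-DMF intervals", {
  persons <- make_person(c("P1", "P2"), c("F", "M"), rep("1985-01-01", 2))
  mk <- function(p, date, surfaces = NA_character_) {
    make_visit("ERA2", person_id = p, visit_date = date, surfaces = surfaces)
  }
  surf11 <- format_surfaces(c(11, 12, 13, 14, 15, 16, 17, 21, 22, 23, 24),
                            rep("O", 11), rep(2, 11))
  v <- dplyr::bind_rows(
    mk("P1", "1995-03-01"),                    # dmf 0
    mk("P1", "1996-03-01", "11:O:2;12:M:1;13:B:4"),  # dmf 3
    mk("P1", "1997-03-01", surf11),            # dmf 11 -> max >= 10
    mk("P2", "1995-06-01"))
  agg <- harmonize_visits(v)
  tab <- mean_entries_by_disease_state(v, agg, persons)
  caries <- tab[tab$disease == "caries", ]
  expect_identical(caries$state[caries$n_individuals == 1 & caries$mean_entries == 3],
                   ">=10")
  expect_setequal(caries$state, c("0-4", ">=10"))
  ging <- tab[tab$disease == "gingivitis", ]
  expect_identical(ging$state, "never")  # nobody flagged
  expect_equal(sum(caries$n_individuals), 2L)
})

test_that("planted differential visit rates order the group means as planted", {
  cfg <- simulation_config(
    n_individuals = 400, birth_year_range = c(1980, 1990),
    visit_schedule = list(annual_p = 0.5, mandatory_p = 0.9, needs_base_p = 0.3,
                          needs_disease_bonus = 0.4),
    prevalence_curves = list(gingivitis = constant_prevalence(0.3),
                             periodontitis = constant_prevalence(0.0),
                             caries = constant_prevalence(0.3)),
    duplicate_rate = 0, faulty_death_rate = 0, faulty_age_rate = 0, seed = 9)
  sim <- simulate_cohort(cfg)
  cl <- clean_pipeline(sim$visits, sim$persons)
  agg <- harmonize_visits(cl$records)
  tab <- mean_entries_by_disease_state(cl$records, agg, sim$persons)
  g <- tab[tab$disease == "gingivitis", ]
  expect_gt(g$mean_entries[g$state == "ever"], g$mean_entries[g$state == "never"])
})
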