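#' Constant latent-prevalence curve
#'
#' Convenience constructor for a prevalence curve that ignores age and
#' calendar year, mainly useful for parameter-recovery experiments.
#'
#' @param p Probability in \[0, 1\].
#' @return A function of `(age, year)` returning `p`.
#' @export
constant_prevalence <- function(p) {
  stopifnot(p >= 0, p <= 1)
  function(age, year) rep(p, length(age))
}

# order-of-magnitude placeholder curves: the source registry publishes its
# prevalence trajectories only as figures, so these defaults are plausible
# shapes, not calibrated values (see the methods vignette)
default_prevalence_curves <- function() {
  ging <- stats::approxfun(c(0, 5, 9, 15, 18), c(0.02, 0.08, 0.25, 0.32, 0.33), rule = 2)
  perio <- stats::approxfun(c(0, 5, 9, 15, 18), c(0, 0.002, 0.01, 0.05, 0.08), rule = 2)
  car <- stats::approxfun(c(0, 2, 5, 9, 15, 18), c(0.01, 0.10, 0.35, 0.45, 0.55, 0.60), rule = 2)
  list(
    gingivitis = function(age, year) ging(age),
    periodontitis = function(age, year) perio(age),
    # secular decline: linear to ~50% of the 1972 level by 2021
    caries = function(age, year) {
      trend <- 1 - 0.5 * pmin(pmax(year - 1972, 0), 49) / 49
      car(age) * trend
    }
  )
}

#' Configuration for the synthetic-registry generator
#'
#' Defines the cohort the generator emulates: who is born when, how often
#' children visit under the annual (pre-1993) and needs-based-with-mandatory-
#' ages (1993 onward) regimes, the latent disease prevalence curves, and the
#' rates at which duplicates and faulty rows are injected. Identical seed
#' and configuration give byte-identical output.
#'
#' @param n_individuals Number of persons (>= 1).
#' @param birth_year_range Integer `c(min, max)` of birth years.
#' @param male_fraction Probability of male sex (default 0.512, matching the
#'   registry's reported sex ratio).
#' @param visit_schedule List with per-age visit probabilities: `annual_p`
#'   (calendar years before 1993), `mandatory_p` (ages 5, 7, 12, 15 from
#'   1993 on), `needs_base_p` (other ages from 1993 on) and
#'   `needs_disease_bonus` (added to `needs_base_p` when any latent disease
#'   is present that age, making visit frequency needs-based).
#' @param prevalence_curves Named list of functions `(age, year) ->
#'   probability` for `gingivitis`, `periodontitis` and `caries`.
#' @param caries_intensity Mean affected surfaces given caries, named
#'   `c(temporary=, permanent=)`.
#' @param persistence Probability of carrying a latent disease state from
#'   one age to the next (disease dynamics; with a constant curve the
#'   marginal prevalence is unaffected).
#' @param detection Probability that a latent-positive visit is coded above
#'   the era's aggregate threshold (1.0 = perfect registration).
#' @param code5_rate Probability that a temporary-dentition caries visit in
#'   ERA2/ERA3 carries extra code-5 surfaces (exercises the registry's own
#'   caries-variant definition, which counts code 5).
#' @param reporting_shock Multiplier on registration probabilities in the
#'   two calendar years after each criteria change (1988-89, 2000-01);
#'   1 = off. Models the hypothesis of overreporting around registration
#'   changes.
#' @param duplicate_rate,faulty_death_rate,faulty_age_rate Per-row injection
#'   probabilities for exact duplicates, death-before-visit faults and
#'   age-out-of-range faults. Their sum must not exceed 1.
#' @param seed Integer RNG seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_individuals,
                              birth_year_range = c(1965L, 2005L),
                              male_fraction = 0.512,
                              visit_schedule = list(annual_p = 0.9,
                                                    mandatory_p = 0.9,
                                                    needs_base_p = 0.45,
                                                    needs_disease_bonus = 0.25),
                              prevalence_curves = default_prevalence_curves(),
                              caries_intensity = c(temporary = 4, permanent = 5),
                              persistence = 0.7,
                              detection = 1.0,
                              code5_rate = 0.05,
                              reporting_shock = 1,
                              duplicate_rate = 0.01,
                              faulty_death_rate = 0.002,
                              faulty_age_rate = 0.003,
                              seed = 1L) {
  stopifnot(n_individuals >= 1,
            length(birth_year_range) == 2L,
            birth_year_range[1] <= birth_year_range[2],
            male_fraction >= 0, male_fraction <= 1,
            persistence >= 0, persistence <= 1,
            detection >= 0, detection <= 1,
            code5_rate >= 0, code5_rate <= 1,
            reporting_shock >= 0,
            all(unlist(visit_schedule) >= 0), all(unlist(visit_schedule) <= 1),
            all(c("gingivitis", "periodontitis", "caries") %in% names(prevalence_curves)))
  rates <- c(duplicate_rate, faulty_death_rate, faulty_age_rate)
  if (any(rates < 0) || sum(rates) > 1) {
    stop("fault-injection rates must be non-negative and sum to at most 1")
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    birth_year_range = as.integer(birth_year_range),
    male_fraction = male_fraction,
    visit_schedule = visit_schedule,
    prevalence_curves = prevalence_curves,
    caries_intensity = caries_intensity,
    persistence = persistence,
    detection = detection,
    code5_rate = code5_rate,
    reporting_shock = reporting_shock,
    duplicate_rate = duplicate_rate,
    faulty_death_rate = faulty_death_rate,
    faulty_age_rate = faulty_age_rate,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# logical n x m matrix marking k[i] positives per row at a random rotation;
# only the count matters downstream, the rotation spreads positives across
# tooth slots
rotation_marks <- function(k, m) {
  n <- length(k)
  offset <- sample.int(m, n, replace = TRUE) - 1L
  col <- matrix(rep(0:(m - 1L), each = n), n, m)
  ((col - offset) %% m) < k
}

#' Emit era-appropriate clinical codings for one latent state
#'
#' Given latent disease indicators and caries severities for a set of
#' visits in one era, draws per-tooth gingiva codes, pocket codes and
#' carious-surface strings under that era's coding scheme. A detected
#' gingivitis-positive visit is coded at or above the era's aggregate
#' threshold (ERA1: four grades totalling >= 9, which includes a grade-3
#' tooth; ERA2: >= 6 teeth code 2; ERA3: >= 6 teeth code 1) and a negative
#' visit strictly below it; analogously for periodontitis (ERA1 `X` flag;
#' ERA2 >= 6 teeth code 5; ERA3 >= 6 indicators). This function consumes
#' the RNG stream.
#'
#' @param latent A data frame with one row per visit: `age`, logical
#'   `ging_pos` and `perio_pos` (already filtered through detection), and
#'   integer `car_temp`, `car_perm` (affected surfaces per dentition).
#' @param era Era label for all rows.
#' @param code5_rate See [simulation_config()].
#' @return A tibble of the era's code columns plus `surfaces`.
#' @export
emit_era_coding <- function(latent, era, code5_rate = 0) {
  n <- nrow(latent)
  era <- match.arg(era, era_levels())
  out <- tibble::tibble(.rows = n)

  if (era == "ERA1") {
    grades <- matrix(NA_character_, n, 4L)
    pos <- latent$ging_pos
    if (any(pos)) {
      g <- matrix(sample(c("2", "3"), sum(pos) * 4L, TRUE, prob = c(0.7, 0.3)),
                  ncol = 4L)
      sev <- sample.int(4L, sum(pos), replace = TRUE)
      g[cbind(seq_len(sum(pos)), sev)] <- "3"
      grades[pos, ] <- g
    }
    if (any(!pos)) {
      grades[!pos, ] <- sample(c("0", "1", "2"), sum(!pos) * 4L, TRUE,
                               prob = c(0.55, 0.30, 0.15))
    }
    temp_set <- latent$age < 6
    for (j in seq_along(TEETH_ERA1)) {
      tooth <- TEETH_ERA1[j]
      col <- rep(NA_character_, n)
      if (j <= 4L) col[temp_set] <- grades[temp_set, j]
      else col[!temp_set] <- grades[!temp_set, j - 4L]
      out[[paste0("ging_", tooth)]] <- col
    }
    out$pato_pocket <- ifelse(latent$perio_pos, "X", NA_character_)
  } else {
    k_pos <- function(flag) {
      k <- integer(n)
      k[flag] <- sample(6:12, sum(flag), TRUE)
      k[!flag] <- sample(0:5, sum(!flag), TRUE,
                         prob = c(0.50, 0.20, 0.12, 0.08, 0.06, 0.04))
      k
    }
    g_marks <- rotation_marks(k_pos(latent$ging_pos), 12L)
    g_code <- if (era == "ERA2") "2" else "1"
    k_perio <- integer(n)
    k_perio[latent$perio_pos] <- sample(6:12, sum(latent$perio_pos), TRUE)
    k_perio[!latent$perio_pos] <- sample(0:5, sum(!latent$perio_pos), TRUE,
                                         prob = c(0.80, 0.10, 0.05, 0.03, 0.01, 0.01))
    p_marks <- rotation_marks(k_perio, 12L)
    p_code <- if (era == "ERA2") "5" else "1"
    p_bg <- if (era == "ERA2") NA_character_ else "0"
    for (j in seq_along(TEETH_12)) {
      tooth <- TEETH_12[j]
      out[[paste0("ging_", tooth)]] <- ifelse(g_marks[, j], g_code, NA_character_)
      out[[paste0("poch_", tooth)]] <- ifelse(p_marks[, j], p_code, p_bg)
    }
  }

  slots_temp <- expand.grid(tooth = fdi_teeth("temporary"),
                            surface = SURFACE_LETTERS, stringsAsFactors = FALSE)
  slots_perm <- expand.grid(tooth = fdi_teeth("permanent"),
                            surface = SURFACE_LETTERS, stringsAsFactors = FALSE)
  surfaces <- rep(NA_character_, n)
  carious <- which(latent$car_temp > 0L | latent$car_perm > 0L)
  for (i in carious) {
    toks <- character(0)
    if (latent$car_temp[i] > 0L) {
      s <- min(latent$car_temp[i], 100L)
      extra5 <- if (era != "ERA1" && code5_rate > 0 && stats::runif(1) < code5_rate)
        sample(1:2, 1) else 0L
      idx <- sample.int(nrow(slots_temp), s + extra5)
      code <- c(sample(c("1", "2", "4", "6"), s, TRUE), rep("5", extra5))
      toks <- c(toks, sprintf("%02d:%s:%s", slots_temp$tooth[idx],
                              slots_temp$surface[idx], code))
    }
    if (latent$car_perm[i] > 0L) {
      s <- min(latent$car_perm[i], 160L)
      idx <- sample.int(nrow(slots_perm), s)
      toks <- c(toks, sprintf("%02d:%s:%s", slots_perm$tooth[idx],
                              slots_perm$surface[idx],
                              sample(c("1", "2", "4", "6"), s, TRUE)))
    }
    surfaces[i] <- paste(toks, collapse = ";")
  }
  out$surfaces <- surfaces
  out
}

#' Simulate a synthetic registry cohort
#'
#' Generates a person table and era-coded visit records with planted latent
#' disease trajectories, then injects duplicates and faulty rows per the
#' configured rates. Latent disease per (person, age) follows the
#' configured prevalence curves with a persistence term carrying states
#' between ages. Visits follow the annual regime before calendar year 1993
#' and the needs-based regime with mandatory ages 5, 7, 12, 15 thereafter;
#' no visit is emitted before 1972 (the registry's start). Output is
#' deterministic given the configuration seed.
#'
#' @param config A [simulation_config()].
#' @return A list with `persons`, `visits` (combined visit tibble spanning
#'   all eras touched, with an `era` column), `ledger` (a [fault_ledger()]
#'   of injected row indices) and `latent` (the planted truth per person and
#'   age: disease indicators and caries surface counts).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n <- config$n_individuals
    persons <- tibble::tibble(
      person_id = sprintf("P%06d", seq_len(n)),
      sex = sample(c("M", "F"), n, TRUE,
                   prob = c(config$male_fraction, 1 - config$male_fraction)),
      birth_date = as.Date(sprintf(
        "%d-01-01",
        {
          yrs <- seq(config$birth_year_range[1], config$birth_year_range[2])
          yrs[sample.int(length(yrs), n, replace = TRUE)]
        })) +
        sample(0:364, n, TRUE),
      death_date = as.Date(rep(NA_character_, n))
    )

    grid <- tidyr::expand_grid(person = seq_len(n), age = 0:18)
    grid$person_id <- persons$person_id[grid$person]
    grid$birth_date <- persons$birth_date[grid$person]
    grid$visit_date <- grid$birth_date + round(grid$age * 365.25) +
      sample(20:150, nrow(grid), TRUE)
    grid$year <- as.integer(format(grid$visit_date, "%Y"))

    # latent trajectories: fresh Bernoulli draw unless the previous age's
    # state is carried over with probability `persistence`
    latent_states <- function(curve) {
      m <- matrix(FALSE, n, 19L)
      for (a in 0:18) {
        yr <- as.integer(format(persons$birth_date, "%Y")) + a
        p <- pmin(pmax(curve(rep(a, n), yr), 0), 1)
        fresh <- stats::runif(n) < p
        if (a == 0L) m[, 1L] <- fresh
        else {
          carry <- stats::runif(n) < config$persistence
          m[, a + 1L] <- ifelse(carry, m[, a], fresh)
        }
      }
      m
    }
    ging_m <- latent_states(config$prevalence_curves$gingivitis)
    perio_m <- latent_states(config$prevalence_curves$periodontitis)
    car_m <- latent_states(config$prevalence_curves$caries)

    ij <- cbind(grid$person, grid$age + 1L)
    grid$ging <- ging_m[ij]
    grid$perio <- perio_m[ij]
    grid$car <- car_m[ij]
    sev <- integer(nrow(grid))
    sev[grid$car] <- 1L + stats::rpois(sum(grid$car),
                                       mean(config$caries_intensity) - 1)
    perm_share <- pmin(pmax((grid$age - 6) / 7, 0), 1)
    grid$car_perm <- stats::rbinom(nrow(grid), sev, perm_share)
    grid$car_temp <- sev - grid$car_perm

    latent <- tibble::tibble(
      person_id = grid$person_id, age = grid$age,
      gingivitis = grid$ging, periodontitis = grid$perio,
      caries = grid$car,
      caries_temp_surfaces = grid$car_temp,
      caries_perm_surfaces = grid$car_perm
    )

    # visit schedule
    sched <- config$visit_schedule
    mandatory <- grid$age %in% c(5L, 7L, 12L, 15L)
    any_disease <- grid$ging | grid$perio | grid$car
    p_visit <- ifelse(grid$year < 1993L, sched$annual_p,
                      ifelse(mandatory, sched$mandatory_p,
                             pmin(1, sched$needs_base_p +
                                    sched$needs_disease_bonus * any_disease)))
    keep <- stats::runif(nrow(grid)) < p_visit & grid$visit_date >= as.Date("1972-01-01")
    vg <- grid[keep, , drop = FALSE]
    if (nrow(vg) == 0L) {
      stop("configuration produced no visits (check birth years and schedule)")
    }
    vg$era <- era_of(vg$visit_date)

    # detection, with optional reporting shock in the two years after each
    # criteria change
    m <- config$reporting_shock
    shock <- m != 1 & vg$year %in% c(1988L, 1989L, 2000L, 2001L)
    det <- pmin(1, config$detection * ifelse(shock, m, 1))
    fp <- ifelse(shock, pmin(1, pmax(m - 1, 0) * 0.05), 0)
    vg$ging_pos <- ifelse(vg$ging, stats::runif(nrow(vg)) < det,
                          stats::runif(nrow(vg)) < fp)
    vg$perio_pos <- ifelse(vg$perio, stats::runif(nrow(vg)) < det,
                           stats::runif(nrow(vg)) < fp)

    # era-appropriate coding
    coded <- vector("list", 3L)
    for (e in era_levels()) {
      rows <- which(vg$era == e)
      if (length(rows) == 0L) next
      codes <- emit_era_coding(
        tibble::tibble(age = vg$age[rows], ging_pos = vg$ging_pos[rows],
                       perio_pos = vg$perio_pos[rows],
                       car_temp = vg$car_temp[rows], car_perm = vg$car_perm[rows]),
        e, config$code5_rate)
      codes$.row <- rows
      coded[[e]] <- codes
    }
    codes_all <- dplyr::bind_rows(coded)
    codes_all <- codes_all[order(codes_all$.row), , drop = FALSE]
    codes_all$.row <- NULL

    month <- as.integer(format(vg$visit_date, "%m"))
    visits <- dplyr::bind_cols(tibble::tibble(
      person_id = vg$person_id,
      visit_date = vg$visit_date,
      era = vg$era,
      # report year followed the school year before 1988, the calendar year
      # 1988-1999, and disappears from 2000 on
      report_year = dplyr::case_when(
        vg$year < 1988L ~ vg$year + as.integer(month >= 8L),
        vg$year < 2000L ~ vg$year,
        TRUE ~ NA_integer_),
      municipality_code = sample(101:850, n, TRUE)[match(vg$person_id, persons$person_id)]
    ), codes_all)

    faulted <- inject_faults(visits, persons, config)
    list(persons = faulted$persons, visits = faulted$visits,
         ledger = faulted$ledger, latent = latent)
  })
}

#' Ground-truth ledger of injected faults
#'
#' @param duplicates,death_before_visit,age_out_of_range Integer row indices
#'   into the emitted visit table. The three sets must be disjoint.
#' @return A `fault_ledger` list.
#' @export
fault_ledger <- function(duplicates = integer(),
                         death_before_visit = integer(),
                         age_out_of_range = integer()) {
  x <- list(duplicates = as.integer(duplicates),
            death_before_visit = as.integer(death_before_visit),
            age_out_of_range = as.integer(age_out_of_range))
  all_rows <- unlist(x)
  if (anyDuplicated(all_rows)) stop("fault ledger classes must be disjoint")
  structure(x, class = "fault_ledger")
}

#' @export
print.fault_ledger <- function(x, ...) {
  cat("Fault ledger:", length(x$duplicates), "duplicates,",
      length(x$death_before_visit), "death-before-visit,",
      length(x$age_out_of_range), "age-out-of-range rows\n")
  invisible(x)
}

#' Inject duplicates and faulty rows into clean visit records
#'
#' Mutates sampled rows into the two faulty classes and appends exact
#' duplicate copies, recording ground truth in a [fault_ledger()].
#' Age faults move the visit to an ineligible age (>= 19, or exactly 0 when
#' the birth year permits) and blank the clinical codes under the era of the
#' mutated date, at most one per person. Death faults assign the person a
#' death date the day before their last visit, making exactly that row
#' faulty; persons holding an age fault are excluded. Duplicates are
#' appended at the end of the table, so ledger conservation holds: emitted
#' rows = clean rows + duplicates.
#'
#' @param visits A clean combined visit tibble (with `era`).
#' @param persons The person tibble (death dates may be assigned).
#' @param config A [simulation_config()]; only the three rates are used.
#' @return A list with `visits`, `persons` and `ledger`. Note this consumes
#'   the RNG stream; [simulate_cohort()] calls it under the configured seed.
#' @export
inject_faults <- function(visits, persons, config) {
  n <- nrow(visits)
  visits <- visits
  persons <- persons
  age_rows <- integer(0)
  death_rows <- integer(0)

  if (config$faulty_age_rate > 0 && n > 0L) {
    cand <- which(stats::runif(n) < config$faulty_age_rate)
    cand <- cand[!duplicated(visits$person_id[cand])]  # one per person
    if (length(cand) > 0L) {
      birth <- persons$birth_date[match(visits$person_id[cand], persons$person_id)]
      birth_year <- as.integer(format(birth, "%Y"))
      orig_age <- as.integer(round(age_at_visit(visits$visit_date[cand], birth)))
      to_zero <- birth_year >= 1972L & stats::runif(length(cand)) < 0.5
      new_date <- as.Date(ifelse(to_zero, as.numeric(birth),
                                 as.numeric(birth) + round(19.25 * 365.25) + orig_age),
                          origin = "1970-01-01")
      visits$visit_date[cand] <- new_date
      new_era <- era_of(new_date)
      code_cols <- setdiff(names(visits),
                           c("person_id", "visit_date", "era", "report_year",
                             "municipality_code"))
      for (col in code_cols) visits[[col]][cand] <- NA_character_
      # re-emit as all-blank under the new era so per-era files stay valid
      visits$era[cand] <- new_era
      age_rows <- cand
    }
  }

  if (config$faulty_death_rate > 0 && n > 0L) {
    excluded_persons <- visits$person_id[age_rows]
    ord <- order(visits$person_id, visits$visit_date)
    last <- ord[cumsum(rle(visits$person_id[ord])$lengths)]
    last <- setdiff(last, age_rows)
    last <- last[!visits$person_id[last] %in% excluded_persons]
    if (length(last) > 0L) {
      p_row <- min(1, config$faulty_death_rate * n / length(last))
      pick <- last[stats::runif(length(last)) < p_row]
      if (length(pick) > 0L) {
        pid <- visits$person_id[pick]
        persons$death_date[match(pid, persons$person_id)] <-
          visits$visit_date[pick] - 1L
        death_rows <- pick
      }
    }
  }

  dup_rows <- integer(0)
  if (config$duplicate_rate > 0 && n > 0L) {
    pick <- which(stats::runif(nrow(visits)) < config$duplicate_rate)
    if (length(pick) > 0L) {
      visits <- dplyr::bind_rows(visits, visits[pick, , drop = FALSE])
      dup_rows <- seq(n + 1L, length.out = length(pick))
    }
  }

  list(visits = visits, persons = persons,
       ledger = fault_ledger(duplicates = dup_rows,
                             death_before_visit = death_rows,
                             age_out_of_range = age_rows))
}
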