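# Build a minimal visit tibble for an era, all codes blank unless given.
# Code columns are passed as named arguments, e.g. ging_16 = "3".
make_visit <- function(era = "ERA2", person_id = "P1", visit_date = NULL,
                       report_year = NA_integer_, municipality_code = 101L,
                       surfaces = NA_character_, ...) {
  if (is.null(visit_date)) {
    visit_date <- switch(era, ERA1 = "1980-06-01", ERA2 = "1995-06-01",
                         ERA3 = "2010-06-01")
  }
  schema <- dialect_schema(switch(era, ERA1 = "era1", ERA2 = "era2", ERA3 = "era3"))
  row <- tibble::tibble(
    person_id = person_id,
    visit_date = as.Date(visit_date),
    era = era,
    report_year = as.integer(report_year),
    municipality_code = as.integer(municipality_code),
    surfaces = surfaces
  )
  for (col in c(schema$gingiva_cols, schema$pocket_cols)) {
    row[[col]] <- NA_character_
  }
  extra <- list(...)
  for (nm in names(extra)) row[[nm]] <- as.character(extra[[nm]])
  row
}

make_person <- function(person_id = "P1", sex = "F", birth_date = "1980-01-01",
                        death_date = NA) {
  tibble::tibble(
    person_id = person_id, sex = sex,
    birth_date = as.Date(birth_date),
    death_date = as.Date(death_date)
  )
}

# independent naive re-counts used as oracles against the harmonization path
naive_gingivitis_score <- function(era, codes) {
  s <- 0L
  for (c in codes) {
    if (is.na(c)) next
    if (era == "ERA1") s <- s + as.integer(c)
    if (era == "ERA2" && c == "2") s <- s + 1L
    if (era == "ERA3" && c == "1") s <- s + 1L
  }
  s
}

naive_pocket_count <- function(era, codes) {
  s <- 0L
  for (c in codes) {
    if (is.na(c)) next
    if (era == "ERA2" && c == "5") s <- s + 1L
    if (era == "ERA3" && c == "1") s <- s + 1L
  }
  s
}

naive_dmf <- function(surfaces_string, dentition, era, variant = "international") {
  if (is.na(surfaces_string) || surfaces_string == "") return(0L)
  s <- 0L
  for (tok in strsplit(surfaces_string, ";")[[1]]) {
    parts <- strsplit(tok, ":")[[1]]
    quad <- as.integer(substr(parts[1], 1, 1))
    dent <- if (quad <= 4) "permanent" else "temporary"
    code <- as.integer(parts[3])
    qual <- code %in% c(1, 2, 4, 6) ||
      (variant == "scor_provided" && code == 5 && dent == "temporary" && era != "ERA1")
    if (dent == dentition && qual) s <- s + 1L
  }
  s
}
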