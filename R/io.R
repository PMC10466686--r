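#' @importFrom rlang .data
NULL

TEETH_12 <- c(11L, 12L, 21L, 22L, 31L, 32L, 41L, 42L, 16L, 26L, 36L, 46L)
TEETH_ERA1 <- c(52L, 55L, 82L, 85L, 12L, 16L, 42L, 46L)
SURFACE_LETTERS <- c("M", "D", "B", "L", "O")  # mesial, distal, buccal, lingual, occlusal
CARIES_CODES <- c("0", "1", "2", "4", "5", "6")

#' Column schema and code alphabets of an era dialect
#'
#' Each era writes a different delimited-text dialect: ERA1 carries gingiva
#' grades on eight index-tooth slots (four per dentition) plus a record-level
#' pathological-pockets flag; ERA2/ERA3 carry per-tooth gingiva and pocket
#' codes on the twelve permanent index teeth. All dialects share the
#' identifying columns and a compact `surfaces` column holding carious
#' tooth surfaces as `tooth:surface:code` triplets separated by `;`
#' (e.g. `"16:O:2;26:M:1"`; sound surfaces are not listed).
#'
#' @param dialect `"era1"`, `"era2"` or `"era3"`.
#' @return A list with elements `era`, `columns` (mandatory column names, in
#'   order), `gingiva_cols`, `pocket_cols`, `gingiva_alphabet`,
#'   `pocket_alphabet`. Blank cells encode the "blank" code.
#' @export
dialect_schema <- function(dialect = c("era1", "era2", "era3")) {
  dialect <- match.arg(dialect)
  id_cols <- c("person_id", "visit_date", "report_year", "municipality_code")
  if (dialect == "era1") {
    ging <- paste0("ging_", TEETH_ERA1)
    list(
      era = "ERA1",
      columns = c(id_cols, ging, "pato_pocket", "surfaces"),
      gingiva_cols = ging,
      pocket_cols = "pato_pocket",
      gingiva_alphabet = c("0", "1", "2", "3"),
      pocket_alphabet = "X"
    )
  } else {
    ging <- paste0("ging_", TEETH_12)
    poch <- paste0("poch_", TEETH_12)
    list(
      era = if (dialect == "era2") "ERA2" else "ERA3",
      columns = c(id_cols, ging, poch, "surfaces"),
      gingiva_cols = ging,
      pocket_cols = poch,
      gingiva_alphabet = if (dialect == "era2") c("1", "2", "X") else c("1", "X"),
      pocket_alphabet = if (dialect == "era2") c("4", "5", "X") else c("0", "1", "X")
    )
  }
}

era_dialect <- function(era) c(ERA1 = "era1", ERA2 = "era2", ERA3 = "era3")[[era]]

delim_for <- function(path) {
  if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Parse a compact surfaces string into a surface table
#'
#' @param surfaces Character vector of `tooth:surface:code` triplet strings
#'   (`NA` or `""` means no carious surfaces registered).
#' @return A tibble with columns `row` (index into `surfaces`), `tooth`
#'   (FDI integer), `surface` (one of M, D, B, L, O) and `code` (integer
#'   caries code). Malformed tokens raise an error naming the offending
#'   entry.
#' @export
#' @examples
#' parse_surfaces("16:O:2;26:M:1")
parse_surfaces <- function(surfaces) {
  surfaces <- as.character(surfaces)
  keep <- which(!is.na(surfaces) & surfaces != "")
  if (length(keep) == 0L) {
    return(tibble::tibble(row = integer(), tooth = integer(),
                          surface = character(), code = integer()))
  }
  toks <- strsplit(surfaces[keep], ";", fixed = TRUE)
  n_tok <- lengths(toks)
  flat <- unlist(toks, use.names = FALSE)
  ok <- grepl("^[0-9]{2}:[MDBLO]:[0-9]$", flat)
  if (!all(ok)) {
    stop("malformed surface tokens: ", paste(head(unique(flat[!ok]), 5), collapse = ", "))
  }
  parts <- matrix(unlist(strsplit(flat, ":", fixed = TRUE)), ncol = 3, byrow = TRUE)
  out <- tibble::tibble(
    row = rep(keep, n_tok),
    tooth = as.integer(parts[, 1]),
    surface = parts[, 2],
    code = as.integer(parts[, 3])
  )
  bad_tooth <- !is_valid_fdi(out$tooth)
  if (any(bad_tooth)) {
    stop("surface tokens name invalid FDI teeth: ",
         paste(head(unique(out$tooth[bad_tooth]), 5), collapse = ", "))
  }
  bad_code <- !as.character(out$code) %in% CARIES_CODES
  if (any(bad_code)) {
    stop("surface caries codes outside alphabet {0,1,2,4,5,6}: ",
         paste(head(unique(out$code[bad_code]), 5), collapse = ", "))
  }
  out
}

#' Serialize a surface table back to compact strings
#'
#' Inverse of [parse_surfaces()] for a single visit.
#'
#' @param tooth,surface,code Parallel vectors for one visit's carious
#'   surfaces.
#' @return A single string, `""` when empty.
#' @export
format_surfaces <- function(tooth, surface, code) {
  if (length(tooth) == 0L) return("")
  paste(sprintf("%02d:%s:%d", as.integer(tooth), surface, as.integer(code)),
        collapse = ";")
}

#' Validate a raw visit table against an era dialect
#'
#' Checks mandatory columns, date parsing, era membership of the visit date,
#' and closed code alphabets (any symbol outside an alphabet is an error,
#' never silently coerced). Municipality codes outside the plausible range
#' 101-900 are flagged as warnings but retained.
#'
#' @param raw A data frame of character columns, as read from file.
#' @param dialect `"era1"`, `"era2"` or `"era3"`.
#' @return A tibble of problems with columns `row`, `column`, `severity`
#'   (`"error"` or `"warning"`) and `message`; zero rows when the table is
#'   valid.
#' @export
validate_visits <- function(raw, dialect) {
  schema <- dialect_schema(dialect)
  missing_cols <- setdiff(schema$columns, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory columns for dialect ", dialect, ": ",
         paste(missing_cols, collapse = ", "))
  }
  probs <- list()
  add <- function(rows, column, severity, message) {
    if (length(rows) > 0L) {
      probs[[length(probs) + 1L]] <<- tibble::tibble(
        row = as.integer(rows), column = column,
        severity = severity, message = message)
    }
  }
  blankish <- function(x) is.na(x) | x == ""

  pid <- as.character(raw$person_id)
  add(which(blankish(pid)), "person_id", "error", "empty person_id")

  d <- as.Date(as.character(raw$visit_date), format = "%Y-%m-%d")
  add(which(is.na(d)), "visit_date", "error", "unparseable date (expect YYYY-MM-DD)")
  yr <- as.integer(format(d, "%Y"))
  in_era <- switch(schema$era,
    ERA1 = yr >= 1972L & yr <= 1987L,
    ERA2 = yr >= 1988L & yr <= 1999L,
    ERA3 = yr >= 2000L)
  add(which(!is.na(d) & !in_era), "visit_date", "error",
      paste0("visit year outside ", schema$era, " range"))

  ry <- as.character(raw$report_year)
  ry_bad <- !blankish(ry) & is.na(suppressWarnings(as.integer(ry)))
  add(which(ry_bad), "report_year", "error", "not an integer year")

  mc <- suppressWarnings(as.integer(as.character(raw$municipality_code)))
  mc_given <- !blankish(as.character(raw$municipality_code))
  add(which(mc_given & is.na(mc)), "municipality_code", "error", "not an integer")
  add(which(mc_given & !is.na(mc) & (mc < 101L | mc > 900L)), "municipality_code",
      "warning", "municipality code outside plausible range; retained")

  for (col in schema$gingiva_cols) {
    x <- as.character(raw[[col]])
    bad <- !blankish(x) & !x %in% schema$gingiva_alphabet
    add(which(bad), col, "error",
        paste0("gingiva code outside {", paste(schema$gingiva_alphabet, collapse = ","), "}"))
  }
  for (col in schema$pocket_cols) {
    x <- as.character(raw[[col]])
    bad <- !blankish(x) & !x %in% schema$pocket_alphabet
    add(which(bad), col, "error",
        paste0("pocket code outside {", paste(schema$pocket_alphabet, collapse = ","), "}"))
  }

  s <- as.character(raw$surfaces)
  s_rows <- which(!blankish(s))
  for (i in s_rows) {
    res <- tryCatch(parse_surfaces(s[i]), error = function(e) conditionMessage(e))
    if (is.character(res)) add(i, "surfaces", "error", res)
  }

  if (length(probs) == 0L) {
    tibble::tibble(row = integer(), column = character(),
                   severity = character(), message = character())
  } else {
    dplyr::arrange(dplyr::bind_rows(probs), .data$row, .data$column)
  }
}

#' Read a visit table in an era dialect
#'
#' Reads a delimited text file (comma for `.csv`, tab for `.tsv`/`.tab`/
#' `.txt`), validates it against the dialect schema, and returns a typed
#' visit tibble with the derived `era` column. Unknown columns are preserved
#' as opaque character extras. Writing with [write_visits()] and re-reading
#' reproduces all fields.
#'
#' @param path Path to the file.
#' @param dialect `"era1"`, `"era2"` or `"era3"`.
#' @param fail_fast If `TRUE` (default) any validation error aborts with a
#'   summary of the per-row problem report; if `FALSE` the offending rows
#'   are dropped and the full report is attached as attribute `"problems"`.
#' @return A visit tibble: `person_id` (character), `visit_date` (`Date`),
#'   `report_year`, `municipality_code` (integer, `NA` when blank), `era`,
#'   the dialect's code columns as character (`NA` = blank), `surfaces`,
#'   then any extra columns.
#' @export
read_visits <- function(path, dialect, fail_fast = TRUE) {
  raw <- readr::read_delim(path, delim = delim_for(path),
                           col_types = readr::cols(.default = readr::col_character()),
                           na = character(), progress = FALSE,
                           show_col_types = FALSE)
  probs <- validate_visits(raw, dialect)
  errs <- probs[probs$severity == "error", ]
  if (nrow(errs) > 0L) {
    if (fail_fast) {
      stop("invalid ", dialect, " file ", path, ": ", nrow(errs), " error(s); first: row ",
           errs$row[1], " column ", errs$column[1], " - ", errs$message[1])
    }
    raw <- raw[-unique(errs$row), , drop = FALSE]
  }
  out <- as_visit_tibble(raw, dialect)
  attr(out, "problems") <- probs
  out
}

# type the raw character table; assumes validation has passed for kept rows
as_visit_tibble <- function(raw, dialect) {
  schema <- dialect_schema(dialect)
  blank_to_na <- function(x) { x <- as.character(x); x[x == ""] <- NA_character_; x }
  out <- tibble::as_tibble(raw)
  out$person_id <- as.character(out$person_id)
  out$visit_date <- as.Date(as.character(out$visit_date), format = "%Y-%m-%d")
  out$report_year <- suppressWarnings(as.integer(blank_to_na(out$report_year)))
  out$municipality_code <- suppressWarnings(as.integer(blank_to_na(out$municipality_code)))
  for (col in c(schema$gingiva_cols, schema$pocket_cols)) {
    out[[col]] <- blank_to_na(out[[col]])
  }
  out$surfaces <- blank_to_na(out$surfaces)
  out$era <- era_of(out$visit_date)
  extras <- setdiff(names(out), c(schema$columns, "era"))
  out[, c(schema$columns[1:2], "era", schema$columns[-(1:2)], extras)]
}

#' Write a visit table in its era dialect
#'
#' @param records A visit tibble as returned by [read_visits()] or
#'   [simulate_cohort()] (single era).
#' @param path Output path; `.csv` writes comma-separated, `.tsv`/`.tab`/
#'   `.txt` tab-separated. Blank cells encode the "blank" code; dates are
#'   ISO 8601.
#' @param dialect Era dialect; defaults to the dialect of the records' era.
#' @return `path`, invisibly.
#' @export
write_visits <- function(records, path, dialect = NULL) {
  if (is.null(dialect)) {
    eras <- unique(records$era)
    if (length(eras) != 1L) {
      stop("records span several eras (", paste(eras, collapse = ", "),
           "); write one era per file or give `dialect` explicitly")
    }
    dialect <- era_dialect(eras)
  }
  schema <- dialect_schema(dialect)
  all_canonical <- unique(c("era", unlist(lapply(c("era1", "era2", "era3"),
                                                 function(d) dialect_schema(d)$columns))))
  extras <- setdiff(names(records), all_canonical)
  out <- records[, c(schema$columns, extras)]
  out$visit_date <- format(out$visit_date, "%Y-%m-%d")
  out[] <- lapply(out, function(x) { x <- as.character(x); x[is.na(x)] <- ""; x })
  if (delim_for(path) == ",") readr::write_csv(out, path) else readr::write_tsv(out, path)
  invisible(path)
}

#' Read and write the person table
#'
#' The person table has one row per individual: `person_id`, `sex`
#' (`F`/`M`), `birth_date`, and optional `death_date` (blank when alive),
#' all dates ISO 8601.
#'
#' @param path Path to a delimited text file.
#' @return For `read_persons()`, a tibble with typed columns. Duplicate
#'   `person_id`s or a death date preceding the birth date are errors.
#' @export
read_persons <- function(path) {
  raw <- readr::read_delim(path, delim = delim_for(path),
                           col_types = readr::cols(.default = readr::col_character()),
                           na = character(), progress = FALSE, show_col_types = FALSE)
  need <- c("person_id", "sex", "birth_date")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop("person table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  out <- tibble::tibble(
    person_id = as.character(raw$person_id),
    sex = as.character(raw$sex),
    birth_date = as.Date(raw$birth_date, format = "%Y-%m-%d"),
    death_date = if ("death_date" %in% names(raw)) {
      dd <- as.character(raw$death_date); dd[dd == ""] <- NA
      as.Date(dd, format = "%Y-%m-%d")
    } else as.Date(rep(NA_character_, nrow(raw)))
  )
  if (anyDuplicated(out$person_id)) {
    stop("person table has duplicated person_id: ",
         paste(head(unique(out$person_id[duplicated(out$person_id)]), 5), collapse = ", "))
  }
  if (!all(out$sex %in% c("F", "M"))) stop("sex must be F or M")
  if (anyNA(out$birth_date)) stop("unparseable birth_date (expect YYYY-MM-DD)")
  bad <- !is.na(out$death_date) & out$death_date < out$birth_date
  if (any(bad)) stop("death_date before birth_date for: ",
                     paste(head(out$person_id[bad], 5), collapse = ", "))
  out
}

#' @rdname read_persons
#' @param persons A person tibble.
#' @export
write_persons <- function(persons, path) {
  out <- persons
  out$birth_date <- format(out$birth_date, "%Y-%m-%d")
  out$death_date <- ifelse(is.na(persons$death_date), "",
                           format(persons$death_date, "%Y-%m-%d"))
  if (delim_for(path) == ",") readr::write_csv(out, path) else readr::write_tsv(out, path)
  invisible(path)
}
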