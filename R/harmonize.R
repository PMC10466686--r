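#' Gingivitis score of one visit
#'
#' Under the 1972-1987 criteria (ERA1) four index teeth are graded 0-3 and
#' the gingivitis index is their sum (0-12). From 1988 (ERA2) the gingivitis
#' level is the number of the twelve index teeth carrying code 2 (bleeding
#' on probing); from 2000 (ERA3) it is the number carrying code 1, the only
#' remaining gingivitis registration. Blank codes count as 0 in every era,
#' as does the missing-tooth code `X`.
#'
#' @param era Era label.
#' @param codes Character (or, for ERA1, numeric) vector of per-tooth codes;
#'   `NA` encodes blank. Codes outside the era's alphabet are an error.
#' @return Integer score in 0-12.
#' @export
#' @examples
#' gingivitis_score("ERA1", c(3, 2, 2, 2))      # 9
#' gingivitis_score("ERA2", c("2", "2", NA))    # 2
gingivitis_score <- function(era, codes) {
  era <- match.arg(era, era_levels())
  codes <- as.character(codes)
  alphabet <- switch(era, ERA1 = c("0", "1", "2", "3"),
                          ERA2 = c("1", "2", "X"),
                          ERA3 = c("1", "X"))
  bad <- !is.na(codes) & !codes %in% alphabet
  if (any(bad)) {
    stop("gingiva code(s) outside ", era, " alphabet: ",
         paste(unique(codes[bad]), collapse = ", "))
  }
  switch(era,
    ERA1 = as.integer(sum(as.integer(codes), na.rm = TRUE)),
    ERA2 = sum(codes == "2", na.rm = TRUE),
    ERA3 = sum(codes == "1", na.rm = TRUE)
  )
}

#' Harmonized gingivitis classification
#'
#' A visit is classified gingivitis-positive when the ERA1 gingivitis index
#' reaches 9 (which forces at least one severely inflamed, grade-3 tooth) or
#' when, from 1988 on, at least 6 of the 12 index teeth carry the positive
#' code.
#'
#' @param era Era label.
#' @param score Integer score from [gingivitis_score()].
#' @return Logical.
#' @export
gingivitis_flag <- function(era, score) {
  era <- match.arg(era, era_levels())
  stopifnot(all(score >= 0 & score <= 12, na.rm = TRUE))
  if (era == "ERA1") score >= 9L else score >= 6L
}

#' Pocket registration summary of one visit
#'
#' ERA1 carries a single record-level pathological-pockets flag: `"X"` when
#' any registration tooth showed pathological pockets, `NA` otherwise (which
#' conflates "healthy" with "not registered"). ERA2 counts the registration
#' teeth with code 5 (pockets > 4 mm with attachment loss); code 4 (pockets
#' > 4 mm without attachment loss) does not count. ERA3 sums the twelve
#' per-tooth pocket indicators; the missing-tooth code `X` counts as 0.
#'
#' @param era Era label.
#' @param codes For ERA1 a single value (`"X"` or `NA`); otherwise the
#'   per-tooth codes (`NA` = blank).
#' @return For ERA1 `"X"` or `NA_character_`; otherwise an integer 0-12.
#' @export
#' @examples
#' pocket_count("ERA2", c("5", "5", "5", "4", "4", rep(NA, 7)))  # 3
pocket_count <- function(era, codes) {
  era <- match.arg(era, era_levels())
  codes <- as.character(codes)
  if (era == "ERA1") {
    stopifnot(length(codes) == 1L)
    if (!is.na(codes) && codes != "X") {
      stop("ERA1 pathological-pockets flag must be X or blank, got: ", codes)
    }
    return(if (is.na(codes)) NA_character_ else "X")
  }
  alphabet <- if (era == "ERA2") c("4", "5", "X") else c("0", "1", "X")
  bad <- !is.na(codes) & !codes %in% alphabet
  if (any(bad)) {
    stop("pocket code(s) outside ", era, " alphabet: ",
         paste(unique(codes[bad]), collapse = ", "))
  }
  if (era == "ERA2") sum(codes == "5", na.rm = TRUE)
  else sum(codes == "1", na.rm = TRUE)
}

#' Harmonized periodontitis classification
#'
#' ERA1: positive iff the pathological-pockets flag is `"X"` (the
#' registration was non-mandatory, so any registration is taken to indicate
#' significant disease). ERA2/ERA3: positive iff at least 6 of the 12
#' registration teeth carry a pocket registration.
#'
#' @param era Era label.
#' @param count Result of [pocket_count()].
#' @return Logical.
#' @export
periodontitis_flag <- function(era, count) {
  era <- match.arg(era, era_levels())
  if (era == "ERA1") !is.na(count) & count == "X"
  else !is.na(count) & as.integer(count) >= 6L
}

#' Decayed-missing-filled surface count of one visit
#'
#' The DMF-S severity of a visit is the number of tooth surfaces carrying a
#' caries registration, counted separately for the temporary dentition
#' (`dmf_s`, FDI quadrants 5-8) and the permanent dentition (`DMF_S`,
#' quadrants 1-4). The `"international"` variant counts codes 1, 2, 4 and 6,
#' matching the internationally used DMF definition. The `"scor_provided"`
#' variant reproduces the registry's own pre-computed temporary-dentition
#' variables, which from 1988 on additionally count code 5.
#'
#' @param surfaces A `tooth:surface:code` string (see [parse_surfaces()]) or
#'   a data frame with columns `tooth` and `code`.
#' @param dentition `"temporary"` or `"permanent"`.
#' @param era Era label (only relevant to the `scor_provided` variant).
#' @param variant `"international"` (default) or `"scor_provided"`.
#' @return Integer surface count.
#' @export
#' @examples
#' dmf_surfaces("55:O:5;54:M:5", "temporary", "ERA2")                   # 0
#' dmf_surfaces("55:O:5;54:M:5", "temporary", "ERA2", "scor_provided")  # 2
dmf_surfaces <- function(surfaces, dentition = c("permanent", "temporary"),
                         era, variant = c("international", "scor_provided")) {
  dentition <- match.arg(dentition)
  era <- match.arg(era, era_levels())
  variant <- match.arg(variant)
  tab <- if (is.data.frame(surfaces)) surfaces else parse_surfaces(surfaces)
  if (nrow(tab) == 0L) return(0L)
  if (!all(as.character(tab$code) %in% CARIES_CODES)) {
    stop("surface caries codes outside alphabet {0,1,2,4,5,6}")
  }
  qualifying <- c(1L, 2L, 4L, 6L)
  if (variant == "scor_provided" && dentition == "temporary" && era != "ERA1") {
    qualifying <- c(qualifying, 5L)
  }
  keep <- tooth_dentition(tab$tooth) == dentition & tab$code %in% qualifying
  sum(keep)
}

#' Harmonize one visit record into aggregate scores
#'
#' Composes [gingivitis_score()], [gingivitis_flag()], [pocket_count()],
#' [periodontitis_flag()] and [dmf_surfaces()] for a single visit row; see
#' [harmonize_visits()] for the vectorized version and the column contract.
#'
#' @param record A one-row visit tibble.
#' @param variant Caries counting variant, see [dmf_surfaces()].
#' @return A one-row aggregate tibble.
#' @export
aggregate_visit <- function(record, variant = c("international", "scor_provided")) {
  stopifnot(nrow(record) == 1L)
  harmonize_visits(record, variant = variant)
}

#' Harmonize visit records into era-comparable aggregate variables
#'
#' For every visit, computes the harmonized gingivitis score and flag, the
#' pocket summary and periodontitis flag, and the DMF-S caries counts for
#' both dentitions. Blank registrations score 0 / flag `FALSE` — the
#' registry cannot distinguish a fully healthy dentition from a registration
#' not having been done — so each disease also carries an `*_all_blank`
#' indicator that is `TRUE` when every relevant field of the visit is blank,
#' letting analysts stratify on that ambiguity. For ERA2 the diagnostic
#' `pocket_code4_count` column reports teeth with code 4 (pockets > 4 mm
#' without attachment loss), which never enters any aggregate.
#'
#' @param visits A visit tibble (single era, or several eras row-bound so
#'   that each era's code columns are present where needed).
#' @param variant Caries counting variant, see [dmf_surfaces()].
#' @return A tibble with one row per visit: `person_id`, `visit_date`,
#'   `era`, `gingivitis_score`, `gingivitis_flag`, `gingivitis_all_blank`,
#'   `pathological_pockets` (ERA1 flag, `"X"`/`NA`), `pocket_count`
#'   (integer, `NA` for ERA1), `pocket_code4_count`, `periodontitis_flag`,
#'   `periodontitis_all_blank`, `dmf_s`, `DMF_S`, `dmf_total`,
#'   `caries_variant`.
#' @export
harmonize_visits <- function(visits, variant = c("international", "scor_provided")) {
  variant <- match.arg(variant)
  n <- nrow(visits)
  stopifnot(all(c("person_id", "visit_date", "era", "surfaces") %in% names(visits)))
  era <- visits$era

  code_matrix <- function(cols) {
    cols <- intersect(cols, names(visits))
    if (length(cols) == 0L) return(matrix(NA_character_, n, 0))
    as.matrix(as.data.frame(lapply(visits[cols], as.character),
                            stringsAsFactors = FALSE, check.names = FALSE))
  }
  count_code <- function(m, code) {
    if (ncol(m) == 0L) rep(0L, n) else as.integer(rowSums(m == code, na.rm = TRUE))
  }
  all_blank <- function(m) {
    if (ncol(m) == 0L) rep(TRUE, n) else rowSums(!is.na(m)) == 0L
  }
  check_alphabet <- function(m, rows, alphabet, what) {
    if (ncol(m) == 0L || !any(rows)) return(invisible())
    vals <- m[rows, , drop = FALSE]
    bad <- !is.na(vals) & !vals %in% alphabet
    if (any(bad)) stop(what, " code(s) outside alphabet {",
                       paste(alphabet, collapse = ","), "}: ",
                       paste(unique(vals[bad]), collapse = ", "))
  }

  is1 <- era == "ERA1"; is2 <- era == "ERA2"; is3 <- era == "ERA3"

  g1 <- code_matrix(paste0("ging_", TEETH_ERA1))
  g12 <- code_matrix(paste0("ging_", TEETH_12))
  check_alphabet(g1, is1, c("0", "1", "2", "3"), "ERA1 gingiva")
  check_alphabet(g12, is2, c("1", "2", "X"), "ERA2 gingiva")
  check_alphabet(g12, is3, c("1", "X"), "ERA3 gingiva")

  g1_num <- matrix(suppressWarnings(as.integer(g1)), n, ncol(g1))
  score1 <- if (ncol(g1)) as.integer(rowSums(g1_num, na.rm = TRUE)) else rep(0L, n)
  ging_score <- rep(NA_integer_, n)
  ging_score[is1] <- score1[is1]
  ging_score[is2] <- count_code(g12, "2")[is2]
  ging_score[is3] <- count_code(g12, "1")[is3]
  ging_blank <- rep(NA, n)
  ging_blank[is1] <- all_blank(g1)[is1]
  ging_blank[is2 | is3] <- all_blank(g12)[is2 | is3]
  ging_flag <- ifelse(is1, ging_score >= 9L, ging_score >= 6L)

  pato <- if ("pato_pocket" %in% names(visits)) as.character(visits$pato_pocket)
          else rep(NA_character_, n)
  if (any(is1 & !is.na(pato) & pato != "X")) {
    stop("ERA1 pathological-pockets flag must be X or blank")
  }
  p12 <- code_matrix(paste0("poch_", TEETH_12))
  check_alphabet(p12, is2, c("4", "5", "X"), "ERA2 pocket")
  check_alphabet(p12, is3, c("0", "1", "X"), "ERA3 pocket")
  pk_count <- rep(NA_integer_, n)
  pk_count[is2] <- count_code(p12, "5")[is2]
  pk_count[is3] <- count_code(p12, "1")[is3]
  code4 <- rep(NA_integer_, n)
  code4[is2] <- count_code(p12, "4")[is2]
  perio_flag <- ifelse(is1, !is.na(pato) & pato == "X", pk_count >= 6L)
  perio_blank <- rep(NA, n)
  perio_blank[is1] <- is.na(pato[is1])
  perio_blank[is2 | is3] <- all_blank(p12)[is2 | is3]
  pato_out <- ifelse(is1, pato, NA_character_)

  surf <- parse_surfaces(visits$surfaces)
  dmf_s <- rep(0L, n); DMF_S <- rep(0L, n)
  if (nrow(surf) > 0L) {
    dent <- tooth_dentition(surf$tooth)
    qual_perm <- surf$code %in% c(1L, 2L, 4L, 6L)
    qual_temp <- qual_perm
    if (variant == "scor_provided") {
      qual_temp <- qual_temp | (surf$code == 5L & era[surf$row] != "ERA1")
    }
    tmp <- surf$row[dent == "temporary" & qual_temp]
    prm <- surf$row[dent == "permanent" & qual_perm]
    if (length(tmp)) { tt <- table(tmp); dmf_s[as.integer(names(tt))] <- as.integer(tt) }
    if (length(prm)) { tt <- table(prm); DMF_S[as.integer(names(tt))] <- as.integer(tt) }
  }

  tibble::tibble(
    person_id = visits$person_id,
    visit_date = visits$visit_date,
    era = era,
    gingivitis_score = ging_score,
    gingivitis_flag = ging_flag,
    gingivitis_all_blank = ging_blank,
    pathological_pockets = pato_out,
    pocket_count = pk_count,
    pocket_code4_count = code4,
    periodontitis_flag = perio_flag,
    periodontitis_all_blank = perio_blank,
    dmf_s = dmf_s,
    DMF_S = DMF_S,
    dmf_total = dmf_s + DMF_S,
    caries_variant = variant
  )
}
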