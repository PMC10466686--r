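#' Registration-criteria eras
#'
#' The registry changed its registration criteria twice, giving three coding
#' regimes ("eras"): ERA1 covers visits 1972-1987, ERA2 1988-1999, and ERA3
#' everything from 2000 on. All harmonization logic in this package is keyed
#' on these eras.
#'
#' @return Character vector of the three era labels, in chronological order.
#' @export
era_levels <- function() c("ERA1", "ERA2", "ERA3")

#' Map a visit date to its registration-criteria era
#'
#' @param visit_date A `Date` vector (or anything coercible via
#'   [as.Date()]). Years before 1972 predate the registry and are rejected.
#' @return Character vector of era labels (`"ERA1"`, `"ERA2"`, `"ERA3"`).
#' @export
#' @examples
#' era_of(as.Date(c("1987-12-31", "1999-06-01", "2000-01-01")))
era_of <- function(visit_date) {
  visit_date <- as.Date(visit_date)
  yr <- as.integer(format(visit_date, "%Y"))
  if (any(yr < 1972L, na.rm = TRUE)) {
    stop("visit dates before 1972 predate the registry: ",
         paste(head(format(visit_date[which(yr < 1972L)]), 5), collapse = ", "))
  }
  out <- rep(NA_character_, length(yr))
  out[yr >= 1972L & yr <= 1987L] <- "ERA1"
  out[yr >= 1988L & yr <= 1999L] <- "ERA2"
  out[yr >= 2000L] <- "ERA3"
  out
}

#' Index teeth examined under each era
#'
#' ERA1 scored four index teeth per dentition (52, 55, 82, 85 in the
#' temporary dentition; 12, 16, 42, 46 in the permanent). From 1988 onward
#' twelve permanent teeth are scored regardless of dentition stage:
#' 11, 12, 21, 22, 31, 32, 41, 42 and the four first molars 16, 26, 36, 46.
#'
#' @param era Era label (`"ERA1"`, `"ERA2"`, `"ERA3"`).
#' @param dentition `"temporary"` or `"permanent"`; only ERA1 distinguishes.
#' @return Integer vector of FDI tooth codes.
#' @export
#' @examples
#' index_teeth("ERA1", "temporary")
#' index_teeth("ERA2")
index_teeth <- function(era, dentition = c("permanent", "temporary")) {
  dentition <- match.arg(dentition)
  era <- match.arg(era, era_levels())
  if (era == "ERA1") {
    if (dentition == "temporary") c(52L, 55L, 82L, 85L) else c(12L, 16L, 42L, 46L)
  } else {
    c(11L, 12L, 21L, 22L, 31L, 32L, 41L, 42L, 16L, 26L, 36L, 46L)
  }
}

#' Substitute a missing ERA1 index tooth by its nearest present neighbor
#'
#' Under the 1972-1987 criteria a missing registration tooth was replaced by
#' the nearest neighboring tooth. The substitute is the present tooth in the
#' same quadrant minimizing absolute position distance; an equidistant tie is
#' broken toward the lower position number. When no tooth in the quadrant is
#' present the tooth is unscorable and `NA` is returned.
#'
#' @param era Must be `"ERA1"`; later eras applied no substitution.
#' @param tooth An ERA1 index tooth (FDI code).
#' @param present_teeth Integer vector of FDI codes present in the mouth.
#' @return The FDI code of the tooth to score, or `NA_integer_` if the
#'   quadrant holds no present tooth (unscorable).
#' @export
#' @examples
#' substitute_missing_index_tooth("ERA1", 16, c(15, 17))  # tie -> 15
substitute_missing_index_tooth <- function(era, tooth, present_teeth) {
  stopifnot(identical(era, "ERA1"))
  tooth <- as.integer(tooth)
  if (!tooth %in% c(index_teeth("ERA1", "permanent"), index_teeth("ERA1", "temporary"))) {
    stop("tooth ", tooth, " is not an ERA1 index tooth")
  }
  present_teeth <- as.integer(present_teeth)
  stopifnot(all(is_valid_fdi(present_teeth)))
  if (tooth %in% present_teeth) return(tooth)
  quadrant <- tooth %/% 10L
  candidates <- present_teeth[present_teeth %/% 10L == quadrant]
  if (length(candidates) == 0L) return(NA_integer_)
  dist <- abs(candidates %% 10L - tooth %% 10L)
  # equidistant neighbors: lower position wins
  candidates <- candidates[order(dist, candidates %% 10L)]
  candidates[[1L]]
}
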