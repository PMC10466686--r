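#' Valid FDI tooth codes
#'
#' All 52 two-digit FDI tooth codes: 32 permanent teeth (quadrants 1-4,
#' positions 1-8) and 20 primary teeth (quadrants 5-8, positions 1-5).
#'
#' @param dentition One of `"all"`, `"permanent"`, `"temporary"`.
#' @return Integer vector of FDI codes.
#' @export
#' @examples
#' length(fdi_teeth())          # 52
#' fdi_teeth("temporary")       # quadrants 5-8
fdi_teeth <- function(dentition = c("all", "permanent", "temporary")) {
  dentition <- match.arg(dentition)
  permanent <- as.integer(outer(1:4 * 10L, 1:8, `+`))
  temporary <- as.integer(outer(5:8 * 10L, 1:5, `+`))
  switch(dentition,
    all = sort(c(permanent, temporary)),
    permanent = sort(permanent),
    temporary = sort(temporary)
  )
}

#' Check FDI tooth codes for validity
#'
#' @param fdi Integer vector of candidate two-digit codes.
#' @return Logical vector; `TRUE` where the code denotes an existing tooth.
#' @export
is_valid_fdi <- function(fdi) {
  fdi <- suppressWarnings(as.integer(fdi))
  q <- fdi %/% 10L
  p <- fdi %% 10L
  !is.na(fdi) &
    ((q >= 1L & q <= 4L & p >= 1L & p <= 8L) |
     (q >= 5L & q <= 8L & p >= 1L & p <= 5L))
}

#' Dentition of an FDI tooth code
#'
#' @param fdi Integer vector of FDI codes.
#' @return Character vector, `"permanent"` (quadrants 1-4) or `"temporary"`
#'   (quadrants 5-8).
#' @export
tooth_dentition <- function(fdi) {
  stopifnot(all(is_valid_fdi(fdi)))
  ifelse(fdi %/% 10L <= 4L, "permanent", "temporary")
}

# Haderup notation places a "+" (maxilla) or "-" (mandible) on the cheek side
# of the position digit: right-side teeth carry the sign after the digit,
# left-side teeth before it. Primary teeth use a leading zero ("05+").
.haderup_sign <- c("+", "+", "-", "-")  # quadrants 1/5, 2/6, 3/7, 4/8

#' Convert FDI tooth codes to Haderup notation
#'
#' The registry's original paper forms used the Danish Haderup tooth
#' numbering; modern exports and this package use FDI. The conversion is a
#' bijection on the 52 valid codes.
#'
#' @param fdi Integer vector of valid FDI codes.
#' @return Character vector of Haderup labels (e.g. `16` -> `"6+"`,
#'   `36` -> `"-6"`, `55` -> `"05+"`).
#' @seealso [haderup_to_fdi()]
#' @export
#' @examples
#' fdi_to_haderup(c(16, 26, 36, 46))
fdi_to_haderup <- function(fdi) {
  fdi <- as.integer(fdi)
  stopifnot(all(is_valid_fdi(fdi)))
  q <- fdi %/% 10L
  p <- fdi %% 10L
  primary <- q >= 5L
  qq <- ifelse(primary, q - 4L, q)  # fold primary quadrants onto 1-4
  digit <- ifelse(primary, sprintf("0%d", p), as.character(p))
  sign <- .haderup_sign[qq]
  right <- qq %in% c(1L, 4L)
  ifelse(right, paste0(digit, sign), paste0(sign, digit))
}

#' Convert Haderup tooth labels to FDI codes
#'
#' @param haderup Character vector of Haderup labels.
#' @return Integer vector of FDI codes.
#' @seealso [fdi_to_haderup()]
#' @export
haderup_to_fdi <- function(haderup) {
  haderup <- as.character(haderup)
  m <- regmatches(haderup, regexec("^([0-9]{1,2})([+-])$|^([+-])([0-9]{1,2})$", haderup))
  out <- vapply(m, function(g) {
    if (length(g) == 0L || g[1] == "") return(NA_integer_)
    if (g[2] != "") { digit <- g[2]; sign <- g[3]; right <- TRUE }
    else            { digit <- g[5]; sign <- g[4]; right <- FALSE }
    primary <- nchar(digit) == 2L
    p <- as.integer(digit)
    if (sign == "+") qq <- if (right) 1L else 2L
    else             qq <- if (right) 4L else 3L
    q <- if (primary) qq + 4L else qq
    fdi <- q * 10L + p
    if (!is_valid_fdi(fdi)) NA_integer_ else fdi
  }, integer(1))
  if (anyNA(out)) {
    bad <- haderup[is.na(out)]
    stop("not valid Haderup tooth labels: ", paste(unique(bad), collapse = ", "))
  }
  out
}
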