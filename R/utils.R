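#' Round half away from zero
#'
#' Base R's `round()` rounds half to even ("banker's rounding"); published
#' pharmacovigilance tables round half away from zero, so 36.875 prints as
#' 36.9. Used for every percentage and statistic the package reports.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(36.875, 1) # 36.9, where round() gives 36.8
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * trunc(abs(x) * scale + 0.5) / scale
}

#' Percentage of a total, rounded half away from zero
#'
#' @param x Numerator count(s).
#' @param total Denominator.
#' @param digits Decimal places (1 for demographic strata, 2 for PT tables).
#' @return `round_half_up(100 * x / total, digits)`.
#' @examples
#' percent(18734, 40545) # 46.2
#' @export
percent <- function(x, total, digits = 1) {
  stopifnot(length(total) == 1, total > 0)
  round_half_up(100 * x / total, digits)
}

# Parse YYYYMMDD strings to integer day keys; unparseable -> NA.
# Comparison uses the integer form directly: 20200315 > 20200101 holds
# as integers because the format is fixed-width big-endian.
parse_fda_dt <- function(x) {
  x <- as.character(x)
  ok <- !is.na(x) & grepl("^[0-9]{8}$", x)
  out <- rep(NA_real_, length(x))
  out[ok] <- as.numeric(x[ok])
  out
}

# Order key for primaryid: numeric when every non-missing id parses as a
# number (modern FAERS), else rank of the lexicographic order (legacy ISRs).
primaryid_key <- function(x) {
  x <- as.character(x)
  num <- suppressWarnings(as.numeric(x))
  if (all(is.na(num) == is.na(x))) num else as.numeric(rank(x, ties.method = "min"))
}

# Uppercase, trim, collapse internal whitespace.
clean_string <- function(x) {
  stringr::str_squish(toupper(as.character(x)))
}
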