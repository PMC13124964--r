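#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used in pharmacovigilance report tables,
#' rather than the banker's rounding of [base::round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, ties away from zero.
#' @examples
#' round_half_up(2.5)        # 3, where round(2.5) is 2
#' round_half_up(41.666, 1)  # 41.7
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a total, rounded half-up
#'
#' @param n count (numeric vector).
#' @param total denominator.
#' @param digits decimal places (default 2, table style; use 1 for prose style).
#' @return `100 * n / total`, rounded half-up.
#' @export
percent_of <- function(n, total, digits = 2) {
  if (total <= 0) return(rep(NA_real_, length(n)))
  round_half_up(100 * n / total, digits)
}

# Trim, collapse internal whitespace, uppercase: the normal form used for
# free-text drug names and for case-insensitive PT comparison.
normalize_name <- function(x) {
  toupper(gsub("\\s+", " ", trimws(x)))
}

# Prefixed progress/accounting messages; everything the pipeline drops is
# announced through here so no row disappears silently.
fs_log <- function(...) {
  message("faersignal: ", ...)
}
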