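#' @keywords internal
"_PACKAGE"

# Error helper: every package error carries a machine-readable class alongside
# the umbrella class "wobblebias_error", so callers can condition on either.
wb_stop <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "wobblebias_error")))
}

wb_assert <- function(ok, class, msg) {
  if (!isTRUE(ok)) wb_stop(class, msg)
  invisible(TRUE)
}

# Round half-up (0.005 -> 0.01), as opposed to base round()'s banker's rounding.
# Used only at the presentation layer; filters and statistics use raw values.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format AA:AG ratio values for reporting
#'
#' Renders ratio values the way result tables print them: finite ratios are
#' rounded half-up to two decimals, the infinite sentinel (no AG-ending codons
#' but at least one AA-ending codon) prints as `"inf"`, and the undefined
#' sentinel (no K/Q/E codons at all) prints as `"NA"`.
#'
#' @param x numeric vector of ratio values (may contain `Inf` and `NaN`).
#' @param digits number of decimals for finite values.
#' @return character vector of the same length.
#' @examples
#' format_ratio(c(2 / 42, Inf, NaN, 1))
#' @export
format_ratio <- function(x, digits = 2) {
  out <- character(length(x))
  fin <- is.finite(x)
  out[fin] <- formatC(round_half_up(x[fin], digits), format = "f", digits = digits)
  out[is.infinite(x)] <- "inf"
  out[is.nan(x) | is.na(x)] <- "NA"
  out
}

# Inverse of format_ratio's sentinel encoding, for reading ratio columns back
# from TSV.
parse_ratio <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  out[x %in% "inf"] <- Inf
  out[is.na(out) & !(x %in% "inf")] <- NaN
  out
}
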