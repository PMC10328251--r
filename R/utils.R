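#' Round half away from zero
#'
#' Percentages in audit reports are conventionally rounded half-up (15.85 ->
#' 15.9), whereas base [round()] uses IEEE round-half-even. A small epsilon
#' guards against binary representation of values such as 0.5 stored as
#' 0.49999....
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(c(15.85, 0.05, 2.345), 1)
round_half_up <- function(x, digits = 1) {
  stopifnot(is.numeric(x), digits >= 0)
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' Percentage with half-up rounding
#' @param num,den Numerator and denominator (vectors recycle).
#' @param digits Decimals to keep.
#' @return `num / den * 100` rounded half-up; `NaN` where `den == 0`.
#' @export
pct_of <- function(num, den, digits = 1) {
  round_half_up(100 * num / den, digits)
}

# Internal: require columns in a data frame, with a caller-facing error.
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Internal: TRUE where a coded value is absent (NA or the OMOP 0 placeholder).
is_none_value <- function(value_concept_id) {
  is.na(value_concept_id) | value_concept_id == 0
}

# Sentinel label under which rows without a coded value are reported.
none_label <- function() "None"
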