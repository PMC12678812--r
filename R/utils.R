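# Shared helpers: term normalization, rounding, composite-field conventions.

# Separator used for every composite field (habitat, datasetName,
# establishmentMeans composite, multi-valued pathway).
SEP <- "; "

#' Normalize a verbatim term for lookup
#'
#' Unicode-normalizes, strips diacritics, collapses internal whitespace,
#' trims, and case-folds. All table lookups (vocabulary terms, location
#' names, restriction lists) key on this normal form, so translation tables
#' do not need to enumerate case or spacing variants.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @export
#' @examples
#' normalize_term(c("  Freshwater ", "NAIVÉ"))
normalize_term <- function(x) {
  x <- stringi::stri_trans_general(as.character(x), "Any-NFC; Latin-ASCII")
  x <- stringr::str_squish(x)
  stringr::str_to_lower(x)
}

#' Round half up
#'
#' Decimal rounding with ties away from zero (round-half-up), the mode used
#' for all reported percentages. Base `round()` rounds half to even, which
#' cannot reproduce conventionally printed shares such as 56.25 -> 56.3.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count over a denominator
#'
#' Returns `100 * count / total` rounded half-up to one decimal; `NA` when
#' the denominator is zero (an empty dataset has no defined shares).
#'
#' @param count,total numeric.
#' @param digits decimal places (default 1).
#' @return numeric.
#' @export
percentage <- function(count, total, digits = 1) {
  ifelse(total == 0, NA_real_, round_half_up(100 * count / total, digits))
}

# Join a character vector into a sorted, deduplicated composite field.
# Empty / NA elements are dropped; an empty result is NA.
join_composite <- function(x) {
  x <- sort(unique(x[!is.na(x) & x != ""]), method = "radix")
  if (length(x) == 0) NA_character_ else paste(x, collapse = SEP)
}

split_composite <- function(x) {
  if (is.na(x) || x == "") return(character(0))
  stringr::str_split_1(x, stringr::fixed(";")) |> stringr::str_squish()
}

# Empty-string <-> NA conversions at the I/O boundary (absent values are
# written as "" in delimited output, not "NA").
na_to_empty <- function(df) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.character), ~ tidyr::replace_na(.x, "")))
}

empty_to_na <- function(x) dplyr::if_else(is.na(x) | x == "", NA_character_, x)

abort_config <- function(msg) rlang::abort(msg, class = "aliendist_config_error")
abort_schema <- function(msg) rlang::abort(msg, class = "aliendist_schema_error")
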