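# First-record date normalization: every parseable date expression is
# reduced to a single integer year. The grammar is explicit and
# config-extensible; anything outside it is reported, never guessed.

#' Normalize first-record dates to single years
#'
#' Grammar, tried in order on the squished input:
#' \itemize{
#'   \item a bare 4-digit year (`"2010"`) is kept as is;
#'   \item a two-year range (`"1900-1910"`, en/em dashes and `"to"` also
#'     accepted) becomes the arithmetic mean of the two years; non-integer
#'     means are truncated toward the earlier year (`"1900-1901"` -> 1900),
#'     consistent with the workflow's earliest-record preference;
#'   \item a full date (`"1987-06-03"`, `"03.06.1987"`, `"06/03/1987"`) is
#'     truncated to its year;
#'   \item a circa prefix (`"c. 1850"`, `"ca 1850"`) is stripped;
#'   \item a decade form (`"1950s"`) becomes the first year of the decade.
#' }
#' Parsed years outside `bounds` are treated as unparseable and reported,
#' not silently dropped.
#'
#' @param verbatim character vector of date expressions.
#' @param bounds plausibility window, default `c(1000, current year)`.
#' @param source_name dataset abbreviation recorded in the report.
#' @return integer vector of years (`NA` where unparseable/empty);
#'   attribute `"report"` lists distinct unparseable expressions with
#'   counts.
#' @export
#' @examples
#' standardize_event_date(c("2010", "1900-1910", "c. 1850", "1950s", "soon"))
standardize_event_date <- function(verbatim,
                                   bounds = c(1000L, as.integer(format(Sys.Date(), "%Y"))),
                                   source_name = NA_character_) {
  x <- stringr::str_squish(tidyr::replace_na(as.character(verbatim), ""))
  x <- stringr::str_replace_all(x, "[–—]", "-")        # en/em dash
  x <- stringr::str_remove(x, stringr::regex("^c(a?)\\.?\\s*", ignore_case = TRUE))
  year <- rep(NA_integer_, length(x))

  is4 <- stringr::str_detect(x, "^\\d{4}$")
  year[is4] <- as.integer(x[is4])

  # decade: 1950s -> 1950
  dec <- is.na(year) & stringr::str_detect(x, "^\\d{4}s$")
  year[dec] <- as.integer(stringr::str_sub(x[dec], 1, 4))

  # range of two 4-digit years; mean truncated toward the earlier year
  rng <- is.na(year) &
    stringr::str_detect(x, "^\\d{4}\\s*(-|to)\\s*\\d{4}$")
  if (any(rng)) {
    m <- stringr::str_match(x[rng], "^(\\d{4})\\s*(?:-|to)\\s*(\\d{4})$")
    y1 <- as.integer(m[, 2]); y2 <- as.integer(m[, 3])
    lo <- pmin(y1, y2)
    year[rng] <- lo + (abs(y2 - y1)) %/% 2L
  }

  # ISO full date YYYY-MM-DD
  iso <- is.na(year) & stringr::str_detect(x, "^\\d{4}-\\d{1,2}-\\d{1,2}$")
  year[iso] <- as.integer(stringr::str_sub(x[iso], 1, 4))

  # day-first or month-first with 4-digit year last: 03.06.1987, 06/03/1987
  dmy <- is.na(year) & stringr::str_detect(x, "^\\d{1,2}[./]\\d{1,2}[./]\\d{4}$")
  year[dmy] <- as.integer(stringr::str_sub(x[dmy], -4))

  out_of_bounds <- !is.na(year) & (year < bounds[1] | year > bounds[2])
  year[out_of_bounds] <- NA_integer_

  unparsed <- x != "" & is.na(year)
  attr(year, "report") <- tibble::tibble(field = "eventDate",
                                         verbatim = x[unparsed],
                                         canonical = NA_character_) |>
    dplyr::count(.data$field, .data$verbatim, .data$canonical, name = "count") |>
    dplyr::mutate(source_name = source_name, matched = FALSE)
  year
}
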