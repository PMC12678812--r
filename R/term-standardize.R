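# Translation-table standardization of status and habitat terms, with
# matched/unmatched reporting. Unmatched terms never drop a record: the
# field is left absent and the verbatim term is exported for review.

#' Standardize verbatim terms against a vocabulary
#'
#' Looks each verbatim value up in the vocabulary's variant map after
#' normalization ([normalize_term()]). A hit yields the canonical term; a
#' miss yields `NA` and is reported. Idempotent on canonical terms.
#'
#' @param verbatim character vector of source terms (may contain `NA`).
#' @param vocab a vocabulary tibble from [vocabulary()] /
#'   [read_translation_table()].
#' @param source_name dataset abbreviation recorded in the report.
#' @return character vector of canonical terms, `NA` where unmatched or
#'   empty; attribute `"report"` holds a [term_match_report()] tibble.
#' @export
#' @examples
#' v <- default_vocabularies()$establishmentMeans
#' standardize_term(c("alien", "Native", "weird-status"), v)
standardize_term <- function(verbatim, vocab, source_name = NA_character_) {
  field <- vocab$field[1] %||% NA_character_
  key <- normalize_term(verbatim)
  idx <- match(key, vocab$variant_norm)
  out <- vocab$canonical[idx]
  out[is.na(verbatim) | key == ""] <- NA_character_
  attr(out, "report") <- term_match_report(field, verbatim, out, source_name)
  out
}

#' Standardize a (possibly multi-valued) habitat field
#'
#' Habitat cells may carry several delimited tokens ("freshwater; marine").
#' Each token is standardized independently against the habitat vocabulary;
#' the result is deduplicated, sorted alphabetically and joined with `"; "`.
#' Habitat describes the taxon, not a single location, so downstream the
#' union over a taxon's records is attached to the taxon.
#'
#' @param verbatim character vector; tokens separated by `delim`.
#' @param vocab habitat vocabulary tibble.
#' @param delim token delimiter (regex), default splits on `;`, `,` or `|`.
#' @param source_name dataset abbreviation recorded in the report.
#' @return character vector of composite canonical habitat values (`NA`
#'   when nothing matched); attribute `"report"` as in [standardize_term()].
#' @export
standardize_habitat <- function(verbatim, vocab, delim = "[;,|]",
                                source_name = NA_character_) {
  tokens <- stringr::str_split(tidyr::replace_na(as.character(verbatim), ""), delim)
  flat <- purrr::map(tokens, ~ stringr::str_squish(.x[.x != "" & !is.na(.x)]))
  std <- purrr::map(flat, function(tk) {
    if (length(tk) == 0) return(character(0))
    vocab$canonical[match(normalize_term(tk), vocab$variant_norm)]
  })
  out <- purrr::map_chr(std, ~ join_composite(.x) %||% NA_character_)
  all_tokens <- unlist(flat, use.names = FALSE)
  all_std <- unlist(std, use.names = FALSE)
  attr(out, "report") <- term_match_report("habitat", all_tokens, all_std, source_name)
  out
}

#' Build a matched/unmatched term report
#'
#' One row per distinct verbatim term observed for a field, with its
#' canonical translation (absent iff unmatched) and occurrence count.
#' The matched and unmatched rows together partition the distinct
#' verbatims observed.
#'
#' @param field field name.
#' @param verbatim observed verbatim values.
#' @param canonical parallel vector of translations (`NA` = unmatched).
#' @param source_name dataset abbreviation the terms came from.
#' @return tibble with columns `field`, `verbatim`, `canonical`,
#'   `source_name`, `count`, `matched`.
#' @export
term_match_report <- function(field, verbatim, canonical,
                              source_name = NA_character_) {
  keep <- !is.na(verbatim) & verbatim != ""
  tibble::tibble(
    field = field,
    verbatim = as.character(verbatim[keep]),
    canonical = as.character(canonical[keep])
  ) |>
    dplyr::count(.data$field, .data$verbatim, .data$canonical,
                 name = "count") |>
    dplyr::mutate(source_name = source_name,
                  matched = !is.na(.data$canonical)) |>
    dplyr::select("field", "verbatim", "canonical", "source_name",
                  "count", "matched")
}
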