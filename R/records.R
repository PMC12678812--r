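# The RawRecord: one source-native occurrence row after column mapping,
# values verbatim. All ingest paths (checklist files, range-map overlay)
# emit this shape; standardization consumes it.

RAW_RECORD_COLS <- c(
  "source_name", "taxon_verbatim", "location_verbatim",
  "establishment_verbatim", "occurrence_verbatim", "degree_verbatim",
  "pathway_verbatim", "habitat_verbatim", "event_date_verbatim",
  "author_hint", "kingdom_hint", "group_hint"
)

#' Construct a tibble of raw occurrence records
#'
#' Fills the canonical raw-record columns, recycling and defaulting missing
#' ones to `NA`. Verbatim values are kept untouched; standardization happens
#' later and reports what it could not translate.
#'
#' @param source_name dataset abbreviation.
#' @param taxon_verbatim,location_verbatim required verbatim fields.
#' @param ... any further raw-record columns (see details).
#' @return tibble with the 12 raw-record columns.
#' @export
raw_records <- function(source_name, taxon_verbatim, location_verbatim, ...) {
  df <- tibble::tibble(source_name = source_name,
                       taxon_verbatim = as.character(taxon_verbatim),
                       location_verbatim = as.character(location_verbatim), ...)
  extra <- setdiff(names(df), RAW_RECORD_COLS)
  if (length(extra)) abort_schema(paste("unknown raw-record columns:", paste(extra, collapse = ", ")))
  for (col in setdiff(RAW_RECORD_COLS, names(df))) df[[col]] <- NA_character_
  df[RAW_RECORD_COLS]
}

as_raw_records <- function(df) {
  for (col in setdiff(RAW_RECORD_COLS, names(df))) df[[col]] <- NA_character_
  tibble::as_tibble(df)[RAW_RECORD_COLS]
}
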