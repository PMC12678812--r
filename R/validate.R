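# Contract enforcement for the two output tables. Every violated rule is
# reported with its table, row and message; an empty report means both
# tables satisfy the published schemas.

#' Validate the two output tables
#'
#' Checks the structural contracts: required columns; uniqueness of
#' `(taxonID, locationID, establishmentMeans)` in the records table;
#' degree/pathway present only on introduced records; non-empty
#' provenance; controlled-vocabulary values; unmatched taxa carrying no
#' backbone-derived fields; unique `taxonID`s and a consistent
#' `(taxonID, taxon)` pairing across tables.
#'
#' @param records records tibble (final schema).
#' @param taxa taxa tibble (final schema).
#' @return tibble with columns `table`, `row`, `rule`, `message`; zero
#'   rows iff everything holds.
#' @export
validate_output_tables <- function(records, taxa) {
  miss_r <- setdiff(RECORD_TABLE_COLS, names(records))
  miss_t <- setdiff(TAXA_TABLE_COLS, names(taxa))
  if (length(miss_r) || length(miss_t)) {
    abort_schema(paste0("missing required column(s): ",
                        paste(c(miss_r, paste0("taxa:", miss_t)), collapse = ", ")))
  }
  v <- list()
  add <- function(tbl, rows, rule, msg) {
    if (length(rows)) {
      v[[length(v) + 1]] <<- tibble::tibble(table = tbl, row = as.integer(rows),
                                            rule = rule, message = msg)
    }
  }

  key <- paste(records$taxonID, records$locationID, records$establishmentMeans)
  add("records", which(duplicated(key) | duplicated(key, fromLast = TRUE)),
      "unique-record-key", "(taxonID, locationID, establishmentMeans) not unique")

  intro <- !is.na(records$establishmentMeans) &
    startsWith(records$establishmentMeans, "introduced")
  add("records",
      which((!is.na(records$degreeOfEstablishment) | !is.na(records$pathway)) & !intro),
      "introduced-only",
      "degreeOfEstablishment/pathway present on a non-introduced record")

  add("records", which(is.na(records$datasetName) | records$datasetName == ""),
      "provenance", "datasetName is empty")
  add("records",
      which(!is.na(records$datasetName) &
              (is.na(records$bibliographicCitation) | records$bibliographicCitation == "")),
      "provenance", "bibliographicCitation is empty")

  em_ok <- c(CANONICAL_TERMS$establishmentMeans, paste0("introduced", SEP, "uncertain"))
  add("records", which(!is.na(records$establishmentMeans) &
                         !records$establishmentMeans %in% em_ok),
      "vocabulary", "establishmentMeans outside the controlled vocabulary")
  add("records", which(!is.na(records$occurrenceStatus) &
                         !records$occurrenceStatus %in% CANONICAL_TERMS$occurrenceStatus),
      "vocabulary", "occurrenceStatus outside the controlled vocabulary")
  add("records", which(!is.na(records$degreeOfEstablishment) &
                         !records$degreeOfEstablishment %in% CANONICAL_TERMS$degreeOfEstablishment),
      "vocabulary", "degreeOfEstablishment outside the controlled vocabulary")
  hab_bad <- which(!is.na(records$habitat) & !vapply(
    records$habitat, function(h) all(split_composite(h) %in% CANONICAL_TERMS$habitat),
    logical(1)))
  add("records", hab_bad, "vocabulary", "habitat outside the controlled vocabulary")

  add("records", which(!is.na(records$eventDate) &
                         (records$eventDate != as.integer(records$eventDate))),
      "event-date", "eventDate is not an integer year")

  missing_tax <- !is.na(taxa$GBIFstatus) & taxa$GBIFstatus == "MISSING"
  derived <- !is.na(taxa$GBIFusageKey) | !is.na(taxa$kingdom) | !is.na(taxa$taxaGroup) |
    !is.na(taxa$GBIFmatchtype) | !is.na(taxa$GBIFtaxonRank)
  add("taxa", which(missing_tax & derived), "missing-no-backbone",
      "unmatched taxon carries backbone-derived fields")

  add("taxa", which(duplicated(taxa$taxonID) | duplicated(taxa$taxonID, fromLast = TRUE)),
      "unique-taxon-id", "taxonID not unique in taxa table")

  pairing <- dplyr::distinct(taxa, .data$taxonID, .data$taxon)
  rec_pairs <- dplyr::distinct(records, .data$taxonID, .data$taxon)
  bad_pair <- dplyr::anti_join(rec_pairs, pairing, by = c("taxonID", "taxon"))
  if (nrow(bad_pair)) {
    add("records", match(paste(bad_pair$taxonID, bad_pair$taxon),
                         paste(records$taxonID, records$taxon)),
        "taxon-id-pairing", "(taxonID, taxon) pairing differs from taxa table")
  }
  orphan <- setdiff(records$taxonID, taxa$taxonID)
  add("records", which(records$taxonID %in% orphan), "taxon-id-resolves",
      "taxonID not present in taxa table")

  if (length(v)) dplyr::bind_rows(v) else {
    tibble::tibble(table = character(0), row = integer(0),
                   rule = character(0), message = character(0))
  }
}
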