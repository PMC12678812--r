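# File output: the two main tables plus the per-field term reports, the
# unmatched-locations report and the exclusion report. Absent values are
# written as empty strings (unambiguous round-trip); output is UTF-8,
# comma-separated, RFC-4180 quoted, and byte-identical across reruns on
# identical input.

#' Write the output file set
#'
#' @param records records tibble (final schema).
#' @param taxa taxa tibble (final schema).
#' @param reports named list of report tibbles: `term_reports` (one tibble
#'   per standardized field), `unmatched_locations`, `exclusions`,
#'   `ingest_log`, `status_conflicts` (missing entries are skipped).
#' @param dir destination directory (created if needed; must be writable
#'   -- checked before any main table is written).
#' @param records_file,taxa_file main output filenames.
#' @return invisibly, a character vector of all written paths.
#' @export
write_outputs <- function(records, taxa, reports = list(), dir,
                          records_file = "aliendist_records.csv",
                          taxa_file = "aliendist_taxa.csv") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  probe <- file.path(dir, ".write_probe")
  ok <- tryCatch({ file.create(probe, showWarnings = FALSE) }, error = function(e) FALSE)
  if (!isTRUE(ok)) rlang::abort(sprintf("destination not writable: %s", dir),
                                class = "aliendist_io_error")
  unlink(probe)

  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(dir, name)
    readr::write_csv(na_to_empty(tibble::as_tibble(df)), p, na = "", progress = FALSE)
    paths <<- c(paths, p)
  }
  emit(records, records_file)
  emit(taxa, taxa_file)
  for (field in names(reports$term_reports %||% list())) {
    emit(reports$term_reports[[field]], sprintf("report_terms_%s.csv", field))
  }
  if (!is.null(reports$unmatched_locations)) {
    emit(reports$unmatched_locations, "report_unmatched_locations.csv")
  }
  if (!is.null(reports$exclusions)) emit(reports$exclusions, "report_exclusions.csv")
  if (!is.null(reports$ingest_log)) emit(reports$ingest_log, "report_ingest_log.csv")
  if (!is.null(reports$status_conflicts)) {
    emit(reports$status_conflicts, "report_status_conflicts.csv")
  }
  invisible(paths)
}

#' Read back a written output table
#'
#' Inverse of [write_outputs()] for the two main tables: empty strings
#' become `NA`, identifier and year columns become integers, so a
#' write-read round trip is lossless field by field.
#'
#' @param path csv path.
#' @return tibble.
#' @export
read_output_table <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"), na = character(0),
                        progress = FALSE, show_col_types = FALSE)
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.character), empty_to_na))
  for (col in intersect(c("locationID", "taxonID", "eventDate", "GBIFusageKey"), names(df))) {
    df[[col]] <- as.integer(df[[col]])
  }
  df
}
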