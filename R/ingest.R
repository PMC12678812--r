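# Declarative per-source ingestion. Each source dataset is described by a
# SourceConfig (column mapping, scope, keep/drop filters, establishment
# encoding, citation); new sources are added by configuration, not code.
# Per-source inclusion rules (e.g. keep only records flagged "established
# outdoors"; keep introduced = 0 and drop location_doubtful rows) are
# expressed as keep_rules / drop_rules on raw columns.

#' Declare a source dataset
#'
#' @param source_name dataset abbreviation used in `datasetName`.
#' @param citation full bibliographic citation echoed into
#'   `bibliographicCitation`.
#' @param scope `"alien"`, `"native"` or `"mixed"`. For a single-scope
#'   source, records without an establishment value inherit the scope's
#'   value (`"introduced"` / `"native"`); a mixed source must supply an
#'   establishment column.
#' @param column_map named list mapping roles (`taxon`, `location` --
#'   possibly several column names, finest first --, `establishment`,
#'   `occurrence`, `degree`, `pathway`, `habitat`, `event_date`, `author`,
#'   `kingdom`, `group`) to raw column names.
#' @param keep_rules named list: raw column -> allowed values (rows with
#'   other values are dropped).
#' @param drop_rules named list: raw column -> disallowed values.
#' @param establishment_encoding optional named character vector decoding
#'   raw codes (e.g. binary `0`/`1`) to establishment text.
#' @param restrict_to_list optional path to a one-column name-list file;
#'   only taxa on the list (normalized comparison) are kept.
#' @param delim,encoding file delimiter and text encoding.
#' @return a `source_config` object.
#' @export
source_config <- function(source_name, citation, scope = c("mixed", "alien", "native"),
                          column_map, keep_rules = list(), drop_rules = list(),
                          establishment_encoding = NULL, restrict_to_list = NULL,
                          delim = ",", encoding = "UTF-8") {
  scope <- match.arg(scope)
  if (!all(c("taxon", "location") %in% names(column_map))) {
    abort_config(sprintf("source '%s': column_map must map 'taxon' and 'location'", source_name))
  }
  if (scope == "mixed" && !"establishment" %in% names(column_map)) {
    abort_config(sprintf(
      "source '%s': a mixed-scope source must map an 'establishment' column", source_name))
  }
  structure(list(
    source_name = source_name, citation = citation, scope = scope,
    column_map = column_map, keep_rules = keep_rules, drop_rules = drop_rules,
    establishment_encoding = establishment_encoding,
    restrict_to_list = restrict_to_list, delim = delim, encoding = encoding
  ), class = "source_config")
}

#' Read source configurations from a YAML file
#'
#' One structured file lists all sources of a run: a top-level `sources`
#' map whose entries carry the [source_config()] fields (plus `path` and,
#' for range-map sources, `type: range_map` and `origin_keep`).
#'
#' @param path YAML file path.
#' @return named list of `source_config` objects; each carries `$path`
#'   (resolved relative to the YAML file) and optional `$type`,
#'   `$origin_keep` attributes.
#' @export
read_source_configs <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("source config file not found: %s", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$sources)) abort_config("source config file: missing top-level 'sources'")
  base <- dirname(path)
  purrr::imap(y$sources, function(s, nm) {
    cfg <- source_config(
      source_name = s$source_name %||% nm,
      citation = s$citation %||% "",
      scope = s$scope %||% "mixed",
      column_map = s$column_map,
      keep_rules = s$keep_rules %||% list(),
      drop_rules = s$drop_rules %||% list(),
      establishment_encoding = if (!is.null(s$establishment_encoding))
        unlist(s$establishment_encoding) else NULL,
      restrict_to_list = if (!is.null(s$restrict_to_list))
        file.path(base, s$restrict_to_list) else NULL,
      delim = s$delim %||% ","
    )
    cfg$path <- if (!is.null(s$path) && !grepl("^/", s$path)) file.path(base, s$path) else s$path
    cfg$type <- s$type %||% "checklist"
    cfg$origin_keep <- unlist(s$origin_keep %||% list())
    cfg
  })
}

#' Load one source dataset as raw records
#'
#' Reads the delimited file, applies the column mapping, combines multiple
#' location columns to the finest available level, applies keep/drop rules
#' and the optional taxon restriction list, decodes establishment codes,
#' and applies scope inheritance. Rows with an empty taxon or (combined)
#' location are dropped and counted.
#'
#' @param path delimited text file with a header row.
#' @param config a [source_config()].
#' @return raw-record tibble; attribute `"ingest_log"` is a tibble of
#'   per-reason drop counts, attribute `"decode_log"` lists establishment
#'   codes left verbatim.
#' @export
load_source <- function(path, config) {
  if (!file.exists(path)) abort_config(sprintf("source '%s': file not found: %s",
                                               config$source_name, path))
  raw <- readr::read_delim(path, delim = config$delim,
                           col_types = readr::cols(.default = "c"),
                           locale = readr::locale(encoding = config$encoding),
                           progress = FALSE, show_col_types = FALSE)
  cm <- config$column_map
  mapped_cols <- unique(unlist(cm))
  rule_cols <- unique(c(names(config$keep_rules), names(config$drop_rules)))
  miss <- setdiff(c(mapped_cols, rule_cols), names(raw))
  if (length(miss)) {
    abort_config(sprintf("source '%s': mapped column(s) missing from file: %s",
                         config$source_name, paste(miss, collapse = ", ")))
  }

  log <- tibble::tibble(source_name = character(0), reason = character(0), n = integer(0))
  note <- function(reason, n) {
    if (n > 0) log <<- dplyr::add_row(log, source_name = config$source_name,
                                      reason = reason, n = as.integer(n))
    invisible(NULL)
  }

  n0 <- nrow(raw)
  raw <- apply_source_filters(raw, config)
  note("failed_filter", n0 - nrow(raw))

  loc <- combine_location_columns(raw, config)
  taxon <- empty_to_na(raw[[cm$taxon]])
  keep <- !is.na(taxon) & !is.na(loc)
  note("empty_taxon", sum(is.na(taxon)))
  note("empty_location", sum(!is.na(taxon) & is.na(loc)))
  raw <- raw[keep, , drop = FALSE]; loc <- loc[keep]; taxon <- taxon[keep]

  if (!is.null(config$restrict_to_list)) {
    allowed <- normalize_term(readr::read_lines(config$restrict_to_list))
    allowed <- allowed[allowed != ""]
    on_list <- normalize_term(taxon) %in% allowed
    note("not_on_restriction_list", sum(!on_list))
    raw <- raw[on_list, , drop = FALSE]; loc <- loc[on_list]; taxon <- taxon[on_list]
  }

  pull <- function(role) if (!is.null(cm[[role]])) empty_to_na(raw[[cm[[role]]]]) else NA_character_
  rec <- raw_records(
    source_name = config$source_name,
    taxon_verbatim = taxon,
    location_verbatim = loc,
    establishment_verbatim = pull("establishment"),
    occurrence_verbatim = pull("occurrence"),
    degree_verbatim = pull("degree"),
    pathway_verbatim = pull("pathway"),
    habitat_verbatim = pull("habitat"),
    event_date_verbatim = pull("event_date"),
    author_hint = pull("author"),
    kingdom_hint = pull("kingdom"),
    group_hint = pull("group")
  )
  rec <- decode_establishment(rec, config)
  rec <- inherit_scope(rec, config)
  attr(rec, "ingest_log") <- log
  rec
}

#' Apply a source's keep/drop filters
#'
#' Keeps exactly the rows satisfying all keep_rules (column value in the
#' allowed set) and no drop_rules (column value in the disallowed set);
#' comparisons are on normalized terms; row order is preserved. With no
#' rules the input passes through unchanged. Idempotent.
#'
#' @param df data frame holding the rule columns.
#' @param config a [source_config()].
#' @return the filtered data frame.
#' @export
apply_source_filters <- function(df, config) {
  keep <- rep(TRUE, nrow(df))
  for (col in names(config$keep_rules)) {
    allowed <- normalize_term(unlist(config$keep_rules[[col]]))
    keep <- keep & normalize_term(df[[col]]) %in% allowed
  }
  for (col in names(config$drop_rules)) {
    banned <- normalize_term(unlist(config$drop_rules[[col]]))
    keep <- keep & !normalize_term(df[[col]]) %in% banned
  }
  df[keep, , drop = FALSE]
}

#' Decode coded establishment values
#'
#' Some sources code means of establishment as binary flags (e.g. `0` =
#' introduced, `1` = native). The config's `establishment_encoding` maps
#' such codes to text; unknown codes are left verbatim and logged on the
#' `"decode_log"` attribute.
#'
#' @param records raw-record tibble.
#' @param config a [source_config()].
#' @return records with `establishment_verbatim` decoded.
#' @export
decode_establishment <- function(records, config) {
  enc <- config$establishment_encoding
  if (is.null(enc) || nrow(records) == 0) {
    attr(records, "decode_log") <- tibble::tibble(code = character(0), n = integer(0))
    return(records)
  }
  v <- records$establishment_verbatim
  hit <- match(normalize_term(v), normalize_term(names(enc)))
  decoded <- unname(enc[hit])
  unknown <- !is.na(v) & is.na(hit)
  records$establishment_verbatim <- dplyr::coalesce(decoded, v)
  attr(records, "decode_log") <- tibble::tibble(code = v[unknown]) |>
    dplyr::count(.data$code, name = "n")
  records
}

#' Combine multiple location columns to the finest level
#'
#' Sources reporting distributions across several columns (e.g. island and
#' country) are collapsed to a single place name per row: the first
#' non-empty cell in the configured priority order, finest first.
#'
#' @param df raw data frame.
#' @param config a [source_config()] whose `column_map$location` lists the
#'   columns finest-first.
#' @return character vector of combined location values (`NA` when all
#'   cells are empty; such rows are dropped and counted by
#'   [load_source()]).
#' @export
combine_location_columns <- function(df, config) {
  cols <- unlist(config$column_map$location)
  vals <- purrr::map(cols, ~ empty_to_na(df[[.x]]))
  purrr::reduce(vals, dplyr::coalesce)
}

# Scope inheritance: a source declared alien- or native-only may omit the
# establishment column; its records inherit the scope's establishment.
inherit_scope <- function(records, config) {
  if (config$scope == "alien") {
    records$establishment_verbatim <-
      dplyr::coalesce(records$establishment_verbatim, "introduced")
  } else if (config$scope == "native") {
    records$establishment_verbatim <-
      dplyr::coalesce(records$establishment_verbatim, "native")
  }
  records
}
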