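# Controlled vocabularies and translation tables for the invasion-status
# and habitat fields. A vocabulary is a tibble with columns
#   field     -- which output field it standardizes
#   canonical -- the standardized term
#   variant   -- a verbatim variant (normalized form is the lookup key)
# Every canonical term maps to itself, so already-standard input passes
# through unchanged.

VOCAB_FIELDS <- c(
  "occurrenceStatus", "establishmentMeans", "degreeOfEstablishment",
  "pathway", "habitat"
)

CANONICAL_TERMS <- list(
  occurrenceStatus      = c("present", "absent"),
  establishmentMeans    = c("native", "introduced", "vagrant", "uncertain"),
  degreeOfEstablishment = c("established", "reproducing", "invasive"),
  pathway = c(
    "release in nature", "escape from confinement", "transport-contaminant",
    "transport-stowaway", "corridor", "unaided"
  ),
  habitat = c("brackish", "freshwater", "marine", "terrestrial")
)

#' Construct a controlled vocabulary
#'
#' Builds the variant-to-canonical lookup table for one output field. The
#' canonical term set per field is fixed (Darwin Core invasion-status terms
#' plus the four habitat categories); variants extend how verbatim source
#' terms are recognized.
#'
#' @param field one of `"occurrenceStatus"`, `"establishmentMeans"`,
#'   `"degreeOfEstablishment"`, `"pathway"`, `"habitat"`.
#' @param variants named character vector: names are verbatim variants,
#'   values are canonical terms. Canonical self-mappings are added
#'   automatically.
#' @return a tibble with columns `field`, `canonical`, `variant`,
#'   `variant_norm`.
#' @export
#' @examples
#' vocabulary("habitat", c(sea = "marine", land = "terrestrial"))
vocabulary <- function(field, variants = character(0)) {
  field <- match.arg(field, VOCAB_FIELDS)
  canon <- CANONICAL_TERMS[[field]]
  if (length(variants)) {
    bad <- setdiff(unique(unname(variants)), canon)
    if (length(bad)) {
      abort_config(sprintf(
        "vocabulary '%s': variant targets not in canonical set: %s",
        field, paste(bad, collapse = ", ")
      ))
    }
  }
  tbl <- tibble::tibble(
    field = field,
    canonical = c(canon, unname(variants)),
    variant = c(canon, names(variants))
  )
  tbl$variant_norm <- normalize_term(tbl$variant)
  dup <- tbl$variant_norm[duplicated(tbl$variant_norm)]
  # a variant may not point at two canonical terms
  conflict <- unique(dup[vapply(
    dup, function(v) length(unique(tbl$canonical[tbl$variant_norm == v])) > 1, logical(1)
  )])
  if (length(conflict)) {
    abort_config(sprintf(
      "vocabulary '%s': variants mapped to multiple canonical terms: %s",
      field, paste(conflict, collapse = ", ")
    ))
  }
  dplyr::distinct(tbl, .data$variant_norm, .keep_all = TRUE)
}

#' Default vocabularies shipped with the package
#'
#' Translation tables for the five standardized fields, pre-populated with
#' variants commonly found in global distribution datasets (e.g. "alien" ->
#' "introduced", "sea" -> "marine"). Users extend or replace them via
#' [read_translation_table()].
#'
#' @return named list of vocabulary tibbles, one per field.
#' @export
default_vocabularies <- function() {
  list(
    occurrenceStatus = vocabulary("occurrenceStatus", c(
      "extant" = "present", "recorded" = "present", "presence" = "present",
      "locally extinct" = "absent", "extinct" = "absent",
      "eradicated" = "absent", "extirpated" = "absent"
    )),
    establishmentMeans = vocabulary("establishmentMeans", c(
      "alien" = "introduced", "exotic" = "introduced",
      "non-native" = "introduced", "nonnative" = "introduced",
      "naturalised" = "introduced", "naturalized" = "introduced",
      "established" = "introduced", "invasive" = "introduced",
      "indigenous" = "native", "endemic" = "native",
      "native - endemic" = "native", "native - non endemic" = "native",
      "reintroduced" = "native",
      "cryptogenic" = "uncertain", "unknown" = "uncertain",
      "questionable" = "uncertain"
    )),
    degreeOfEstablishment = vocabulary("degreeOfEstablishment", c(
      "naturalized" = "established", "naturalised" = "established",
      "established outdoors" = "established",
      "breeding" = "reproducing", "reproducing in the wild" = "reproducing",
      "widespread invasive" = "invasive"
    )),
    pathway = vocabulary("pathway", c(
      "release" = "release in nature", "escape" = "escape from confinement",
      "contaminant" = "transport-contaminant", "stowaway" = "transport-stowaway",
      "natural dispersal" = "unaided"
    )),
    habitat = vocabulary("habitat", c(
      "sea" = "marine", "oceanic" = "marine", "saltwater" = "marine",
      "land" = "terrestrial", "limnic" = "freshwater",
      "fresh water" = "freshwater", "brackish water" = "brackish"
    ))
  )
}

#' Read a translation table from a delimited file
#'
#' The file format mirrors the workflow's user-editable configuration
#' files: a header row, a `canonical` column, and one or more variant
#' columns (any name); each non-empty variant cell maps to the canonical
#' term on its row. Delimiter is sniffed from the header (comma or tab).
#'
#' @param path file path.
#' @param field which output field the table standardizes.
#' @return a vocabulary tibble (see [vocabulary()]).
#' @export
read_translation_table <- function(path, field) {
  if (!file.exists(path)) abort_config(sprintf("translation table not found: %s", path))
  delim <- if (grepl("\t", readLines(path, n = 1))) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  if (!"canonical" %in% names(raw)) {
    abort_schema(sprintf("translation table %s: missing required column 'canonical'", path))
  }
  long <- tidyr::pivot_longer(raw, -"canonical", values_to = "variant") |>
    dplyr::filter(!is.na(.data$variant), .data$variant != "")
  vocabulary(field, setNames(long$canonical, long$variant))
}

#' Write the default translation tables to a directory
#'
#' Emits one editable delimited file per standardized field, in the format
#' [read_translation_table()] consumes. Useful as a starting point for a
#' custom configuration.
#'
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_translation_tables <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vocabs <- default_vocabularies()
  paths <- purrr::imap_chr(vocabs, function(v, field) {
    wide <- v |>
      dplyr::filter(.data$variant != .data$canonical) |>
      dplyr::group_by(.data$canonical) |>
      dplyr::mutate(col = paste0("variant_", dplyr::row_number())) |>
      dplyr::ungroup() |>
      tidyr::pivot_wider(id_cols = "canonical", names_from = "col",
                         values_from = "variant") |>
      dplyr::right_join(tibble::tibble(canonical = CANONICAL_TERMS[[field]]),
                        by = "canonical")
    p <- file.path(dir, paste0(field, ".csv"))
    readr::write_csv(na_to_empty(wide), p, na = "")
    p
  })
  invisible(paths)
}
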