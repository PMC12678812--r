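# Deterministic merging of standardized records into the final
# distribution table. Grouping key: (taxon, location, establishment
# class), where the class pools "introduced" with "uncertain" (their
# co-occurrence yields the composite "introduced; uncertain") and keeps
# "native" and "vagrant" separate. Within a group: earliest first-record
# year wins, "present" beats "absent" (conflicts logged), degree and
# pathway attach only to introduced records, provenance is the sorted
# union of contributing sources.

DEGREE_ORDER <- c("established", "reproducing", "invasive")

establishment_class <- function(em) {
  dplyr::case_when(
    em == "native" ~ "native",
    em == "vagrant" ~ "vagrant",
    # the composite label is accepted on input so that re-merging merged
    # output is the identity
    em %in% c("introduced", "uncertain", paste0("introduced", SEP, "uncertain")) ~
      "introduced-like",
    TRUE ~ NA_character_
  )
}

#' Merge standardized records into the distribution table
#'
#' @param records tibble of standardized records with columns
#'   `source_name`, `taxon`, `location`, `locationID`,
#'   `establishmentMeans`, `occurrenceStatus`, `degreeOfEstablishment`,
#'   `pathway`, `habitat`, `eventDate`.
#' @param citations named character vector mapping source abbreviations to
#'   full citations.
#' @return merged tibble ordered by (taxon, locationID,
#'   establishmentMeans), with attributes `"exclusions"` (records lacking
#'   a matched location or an establishment value, with reasons) and
#'   `"status_conflicts"` (groups where sources disagreed on
#'   presence/absence).
#' @export
merge_records <- function(records, citations = character(0)) {
  records <- tibble::as_tibble(records)
  records$.class <- establishment_class(records$establishmentMeans)
  excl_reason <- dplyr::case_when(
    is.na(records$locationID) ~ "unmatched location",
    is.na(records$.class) ~ "missing establishmentMeans",
    TRUE ~ NA_character_
  )
  exclusions <- records[!is.na(excl_reason), , drop = FALSE]
  exclusions$reason <- excl_reason[!is.na(excl_reason)]
  ok <- records[is.na(excl_reason), , drop = FALSE]

  # habitat describes the taxon: union over all of the taxon's records
  tax_hab <- ok |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(habitat = join_habitats(.data$habitat), .groups = "drop")

  merged <- ok |>
    dplyr::group_by(.data$taxon, .data$locationID, .data$.class) |>
    dplyr::summarise(
      location = .data$location[1],
      establishmentMeans = combine_establishment(.data$establishmentMeans, .data$.class[1]),
      eventDate = safe_min(.data$eventDate),
      .status_conflict = conflict_occurrence(.data$occurrenceStatus),
      occurrenceStatus = combine_occurrence(.data$occurrenceStatus),
      degreeOfEstablishment = combine_degree(.data$degreeOfEstablishment),
      pathway = join_composite(split_all(.data$pathway)),
      datasetName = join_composite(.data$source_name),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      degreeOfEstablishment = dplyr::if_else(
        startsWith(.data$establishmentMeans, "introduced"),
        .data$degreeOfEstablishment, NA_character_),
      pathway = dplyr::if_else(
        startsWith(.data$establishmentMeans, "introduced"),
        .data$pathway, NA_character_),
      bibliographicCitation = purrr::map_chr(
        .data$datasetName, ~ cite_sources(.x, citations))
    ) |>
    dplyr::left_join(tax_hab, by = "taxon") |>
    dplyr::arrange(.data$taxon, .data$locationID, .data$establishmentMeans)

  conflicts <- merged |>
    dplyr::filter(.data$.status_conflict) |>
    dplyr::select("taxon", "locationID", "establishmentMeans", "datasetName")
  out <- merged |>
    dplyr::select("location", "locationID", "taxon", "eventDate", "habitat",
                  "occurrenceStatus", "establishmentMeans",
                  "degreeOfEstablishment", "pathway", "datasetName",
                  "bibliographicCitation")
  attr(out, "exclusions") <- dplyr::select(exclusions, -".class")
  attr(out, "status_conflicts") <- conflicts
  out
}

combine_establishment <- function(em, class) {
  if (class != "introduced-like") return(class)
  comp <- paste0("introduced", SEP, "uncertain")
  has_i <- any(em %in% c("introduced", comp))
  has_u <- any(em %in% c("uncertain", comp))
  if (has_i && has_u) comp else if (has_i) "introduced" else "uncertain"
}

combine_occurrence <- function(os) {
  if (any(os == "present", na.rm = TRUE)) "present"
  else if (any(os == "absent", na.rm = TRUE)) "absent"
  else NA_character_
}

conflict_occurrence <- function(os) {
  any(os == "present", na.rm = TRUE) && any(os == "absent", na.rm = TRUE)
}

combine_degree <- function(dg) {
  hit <- DEGREE_ORDER[DEGREE_ORDER %in% dg]
  if (length(hit)) hit[length(hit)] else NA_character_
}

safe_min <- function(x) {
  x <- x[!is.na(x)]
  if (length(x)) as.integer(min(x)) else NA_integer_
}

split_all <- function(x) unlist(lapply(x, split_composite))

join_habitats <- function(h) join_composite(split_all(h))

cite_sources <- function(dataset_name, citations) {
  src <- split_composite(dataset_name)
  cites <- unname(citations[src])
  cites[is.na(cites)] <- src[is.na(cites)]
  paste(unique(cites), collapse = SEP)
}

#' Reference implementation of the merge (plain loops)
#'
#' A deliberately naive group-and-combine used by the fixture generator's
#' ground-truth ledger: enumerates merge groups one by one with base-R
#' loops and no shared code with [merge_records()]'s vectorized path.
#'
#' @inheritParams merge_records
#' @return merged tibble, same contract as [merge_records()].
#' @export
merge_records_naive <- function(records, citations = character(0)) {
  records <- as.data.frame(records)
  cls <- establishment_class(records$establishmentMeans)
  keep <- !is.na(records$locationID) & !is.na(cls)
  excl <- records[!keep, , drop = FALSE]
  if (nrow(excl)) {
    excl$reason <- ifelse(is.na(records$locationID[!keep]),
                          "unmatched location", "missing establishmentMeans")
  } else excl$reason <- character(0)
  records <- records[keep, , drop = FALSE]; cls <- cls[keep]

  hab <- list()
  for (i in seq_len(nrow(records))) {
    t <- records$taxon[i]
    hab[[t]] <- union(hab[[t]], split_composite(records$habitat[i]))
  }

  keys <- unique(paste(records$taxon, records$locationID, cls, sep = "\r"))
  rows <- list()
  for (k in sort(keys, method = "radix")) {
    p <- strsplit(k, "\r", fixed = TRUE)[[1]]
    idx <- which(records$taxon == p[1] & records$locationID == as.integer(p[2]) & cls == p[3])
    g <- records[idx, , drop = FALSE]
    ems <- unique(g$establishmentMeans)
    has_i <- any(ems %in% c("introduced", "introduced; uncertain"))
    has_u <- any(ems %in% c("uncertain", "introduced; uncertain"))
    em <- if (p[3] != "introduced-like") p[3]
      else if (has_i && has_u) "introduced; uncertain"
      else if (has_i) "introduced" else "uncertain"
    dates <- g$eventDate[!is.na(g$eventDate)]
    occ <- if ("present" %in% g$occurrenceStatus) "present"
      else if ("absent" %in% g$occurrenceStatus) "absent" else NA_character_
    deg <- NA_character_
    for (d in rev(DEGREE_ORDER)) if (d %in% g$degreeOfEstablishment) { deg <- d; break }
    pw <- sort(unique(unlist(lapply(g$pathway, split_composite))), method = "radix")
    if (!startsWith(em, "introduced")) { deg <- NA_character_; pw <- character(0) }
    srcs <- sort(unique(g$source_name), method = "radix")
    cites <- unname(citations[srcs]); cites[is.na(cites)] <- srcs[is.na(cites)]
    habs <- sort(hab[[p[1]]], method = "radix")
    rows[[k]] <- tibble::tibble(
      location = g$location[1], locationID = as.integer(p[2]), taxon = p[1],
      eventDate = if (length(dates)) as.integer(min(dates)) else NA_integer_,
      habitat = if (length(habs)) paste(habs, collapse = SEP) else NA_character_,
      occurrenceStatus = occ, establishmentMeans = em,
      degreeOfEstablishment = deg,
      pathway = if (length(pw)) paste(pw, collapse = SEP) else NA_character_,
      datasetName = paste(srcs, collapse = SEP),
      bibliographicCitation = paste(unique(cites), collapse = SEP)
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    out <- out[order(out$taxon, out$locationID, out$establishmentMeans,
                     method = "radix"), , drop = FALSE]
  }
  attr(out, "exclusions") <- tibble::as_tibble(excl)
  tibble::as_tibble(out)
}

#' Assign internal identifiers
#'
#' `locationID` is authoritative from the location translation table and
#' already carried by the records. `taxonID` is assigned as consecutive
#' positive integers over the taxa table sorted lexicographically by
#' `(taxon, verbatimTaxonRank)` -- stable across reruns on identical
#' input. Records take the taxonID of the first taxa-table entry whose
#' accepted `taxon` equals theirs, so every taxonID used in the records
#' table appears exactly once in the taxa table.
#'
#' @param records merged records tibble (without `taxonID`).
#' @param taxa taxa tibble from [build_taxa_list()].
#' @return list with elements `records` and `taxa`, both carrying IDs; the
#'   records table is in the final column order.
#' @export
assign_ids <- function(records, taxa) {
  taxa <- dplyr::arrange(taxa, .data$taxon, .data$verbatimTaxonRank)
  taxa$taxonID <- seq_len(nrow(taxa))
  canonical <- taxa |>
    dplyr::distinct(.data$taxon, .keep_all = TRUE) |>
    dplyr::select("taxon", "taxonID")
  records <- records |>
    dplyr::left_join(canonical, by = "taxon") |>
    dplyr::select("location", "locationID", "taxon", "taxonID", "eventDate",
                  "habitat", "occurrenceStatus", "establishmentMeans",
                  "degreeOfEstablishment", "pathway", "datasetName",
                  "bibliographicCitation")
  taxa <- dplyr::select(taxa, dplyr::all_of(TAXA_TABLE_COLS))
  list(records = records, taxa = taxa)
}

TAXA_TABLE_COLS <- c(
  "scientificName", "verbatimTaxonRank", "taxon", "GBIFstatus",
  "GBIFstatus_Synonym", "GBIFmatchtype", "GBIFtaxonRank", "GBIFusageKey",
  "GBIFnote", "species", "genus", "family", "order", "class", "phylum",
  "kingdom", "taxonID", "taxaGroup"
)

RECORD_TABLE_COLS <- c(
  "location", "locationID", "taxon", "taxonID", "eventDate", "habitat",
  "occurrenceStatus", "establishmentMeans", "degreeOfEstablishment",
  "pathway", "datasetName", "bibliographicCitation"
)
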