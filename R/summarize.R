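# Dataset overview statistics. Record-level shares use the record count
# as denominator, taxon-level shares the number of distinct taxa.
# All percentages are rounded half-up to one decimal (stated in the
# report header written by write_outputs()).

#' Summarize the harmonized dataset
#'
#' @param records records tibble (final schema).
#' @param taxa taxa tibble (final schema).
#' @return a `dataset_summary`: list with `stats` (one-row tibble of
#'   counts and percentages), `by_establishment` and `by_taxa_group`
#'   count tables, and `rounding` (documentation of the rounding mode).
#' @export
summarize_dataset <- function(records, taxa) {
  n <- nrow(records)
  n_taxa <- dplyr::n_distinct(taxa$taxon)
  em <- records$establishmentMeans
  comp <- paste0("introduced", SEP, "uncertain")

  by_em <- records |>
    dplyr::count(.data$establishmentMeans, name = "n_records") |>
    dplyr::mutate(pct = percentage(.data$n_records, n))

  alien_taxa <- unique(records$taxon[!is.na(em) & em != "native"])
  native_taxa <- unique(records$taxon[!is.na(em) & em == "native"])
  matched_taxa <- unique(taxa$taxon[taxa$GBIFstatus != "MISSING"])
  habitat_taxa <- unique(records$taxon[!is.na(records$habitat)])

  stats <- tibble::tibble(
    n_records = n,
    n_taxa_total = n_taxa,
    n_taxa_alien_distribution = length(alien_taxa),
    n_taxa_native_distribution = length(native_taxa),
    n_locations = dplyr::n_distinct(records$locationID),
    n_introduced = sum(em == "introduced", na.rm = TRUE),
    pct_introduced = percentage(sum(em == "introduced", na.rm = TRUE), n),
    n_native = sum(em == "native", na.rm = TRUE),
    pct_native = percentage(sum(em == "native", na.rm = TRUE), n),
    n_introduced_uncertain = sum(em == comp, na.rm = TRUE),
    pct_introduced_uncertain = percentage(sum(em == comp, na.rm = TRUE), n),
    n_uncertain = sum(em == "uncertain", na.rm = TRUE),
    pct_uncertain = percentage(sum(em == "uncertain", na.rm = TRUE), n),
    n_vagrant = sum(em == "vagrant", na.rm = TRUE),
    pct_vagrant = percentage(sum(em == "vagrant", na.rm = TRUE), n),
    n_degree = sum(!is.na(records$degreeOfEstablishment)),
    pct_degree = percentage(sum(!is.na(records$degreeOfEstablishment)), n),
    n_occurrence = sum(!is.na(records$occurrenceStatus)),
    pct_occurrence = percentage(sum(!is.na(records$occurrenceStatus)), n),
    n_pathway = sum(!is.na(records$pathway)),
    pct_pathway = percentage(sum(!is.na(records$pathway)), n),
    n_event_date = sum(!is.na(records$eventDate)),
    pct_event_date = percentage(sum(!is.na(records$eventDate)), n),
    n_taxa_with_habitat = length(habitat_taxa),
    pct_taxa_with_habitat = percentage(length(habitat_taxa), n_taxa),
    n_taxa_matched_backbone = length(matched_taxa),
    pct_taxa_matched_backbone = percentage(length(matched_taxa), n_taxa)
  )

  by_group <- taxa |>
    dplyr::filter(!is.na(.data$taxaGroup)) |>
    dplyr::distinct(.data$taxon, .data$taxaGroup) |>
    dplyr::count(.data$taxaGroup, name = "n_taxa") |>
    dplyr::arrange(dplyr::desc(.data$n_taxa))

  structure(list(stats = stats, by_establishment = by_em,
                 by_taxa_group = by_group,
                 rounding = "percentages rounded half-up to one decimal"),
            class = "dataset_summary")
}

#' @export
print.dataset_summary <- function(x, ...) {
  s <- x$stats
  cat("Harmonized distribution dataset\n")
  cat(sprintf("  records: %d across %d locations\n", s$n_records, s$n_locations))
  cat(sprintf("  taxa: %d total (%d alien-distribution, %d native-distribution)\n",
              s$n_taxa_total, s$n_taxa_alien_distribution, s$n_taxa_native_distribution))
  fmt <- function(nm, n, p) sprintf("  %-24s %8d (%s%%)\n", nm, n,
                                    ifelse(is.na(p), "-", format(p)))
  cat(fmt("introduced", s$n_introduced, s$pct_introduced))
  cat(fmt("native", s$n_native, s$pct_native))
  cat(fmt("introduced; uncertain", s$n_introduced_uncertain, s$pct_introduced_uncertain))
  cat(fmt("uncertain", s$n_uncertain, s$pct_uncertain))
  cat(fmt("vagrant", s$n_vagrant, s$pct_vagrant))
  cat(fmt("degreeOfEstablishment", s$n_degree, s$pct_degree))
  cat(fmt("occurrenceStatus", s$n_occurrence, s$pct_occurrence))
  cat(fmt("pathway", s$n_pathway, s$pct_pathway))
  cat(fmt("eventDate", s$n_event_date, s$pct_event_date))
  cat(sprintf("  taxa matched to backbone: %d (%s%%)\n",
              s$n_taxa_matched_backbone,
              ifelse(is.na(s$pct_taxa_matched_backbone), "-",
                     format(s$pct_taxa_matched_backbone))))
  cat(" ", x$rounding, "\n")
  invisible(x)
}
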