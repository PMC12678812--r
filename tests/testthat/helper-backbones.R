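# Backbone construction helpers: concise fixture backbones for the
# matching cascade tests.

bb_row <- function(key, canonical, author = "Author, 1900", status = "ACCEPTED",
                   accepted = key, kingdom = "Animalia", phylum = "Chordata",
                   class = "Aves", rank = "SPECIES") {
  genus <- sub(" .*", "", canonical)
  tibble::tibble(
    usage_key = key,
    scientific_name = paste(canonical, author),
    canonical_name = canonical, authorship = author, rank = rank,
    status = status, accepted_usage_key = accepted,
    kingdom = kingdom, phylum = phylum, class = class,
    order = paste0(genus, "ales"), family = paste0(genus, "idae"),
    genus = genus, species = canonical
  )
}

make_backbone <- function(...) local_backbone(dplyr::bind_rows(...))

# Brute-force matcher: scans every backbone row with the same
# normalization and edit-distance rule, no shared code with match_taxon.
oracle_match_scan <- function(verbatim, table, kingdom_hint = NA) {
  key <- aliendist::normalize_term(gsub("×\\s*", "", verbatim))
  exact <- table[aliendist::normalize_term(table$canonical_name) == key |
                   aliendist::normalize_term(table$scientific_name) == key, ]
  if (nrow(exact) > 1 && !is.na(kingdom_hint)) {
    exact <- exact[tolower(exact$kingdom) == tolower(kingdom_hint), ]
  }
  if (nrow(exact) == 1) {
    final <- if (exact$status == "SYNONYM")
      table[table$usage_key == exact$accepted_usage_key, ] else exact
    return(list(outcome = exact$status, taxon = final$canonical_name,
                key = final$usage_key))
  }
  if (nrow(exact) > 1) return(list(outcome = "HOMONYM", taxon = verbatim, key = NA))
  d <- aliendist::osa_distance(key, aliendist::normalize_term(table$canonical_name))
  close1 <- which(d <= 1)
  if (length(close1) == 1 && sum(d <= 2) == 1) {
    e <- table[close1, ]
    final <- if (e$status == "SYNONYM") table[table$usage_key == e$accepted_usage_key, ] else e
    return(list(outcome = e$status, taxon = final$canonical_name, key = final$usage_key))
  }
  list(outcome = "MISSING", taxon = verbatim, key = NA)
}
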