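# Taxonomic harmonization: exact -> synonym -> fuzzy matching cascade
# against a taxonomy backbone, homonym resolution via source hints,
# authority stripping, and taxa-group assignment.

TAXON_MATCH_COLS <- c(
  "verbatim_name", "taxon", "scientific_name", "status", "status_synonym",
  "match_type", "rank", "usage_key", "note",
  "species", "genus", "family", "order", "class", "phylum", "kingdom",
  "taxa_group"
)

empty_match <- function(verbatim) {
  tibble::tibble(
    verbatim_name = verbatim, taxon = verbatim,
    scientific_name = NA_character_, status = "MISSING",
    status_synonym = NA_character_, match_type = NA_character_,
    rank = NA_character_, usage_key = NA_integer_, note = NA_character_,
    species = NA_character_, genus = NA_character_, family = NA_character_,
    order = NA_character_, class = NA_character_, phylum = NA_character_,
    kingdom = NA_character_, taxa_group = NA_character_
  )
}

#' Match one taxon name against a backbone
#'
#' Cascade: (1) exact lookup -- a single accepted hit is taken as
#' `ACCEPTED`/`EXACT`; a single synonym hit is resolved to its accepted
#' name (`SYNONYM`/`EXACT`, with the synonym's own status recorded);
#' (2) several exact hits are homonyms, resolved with the source hints
#' (author, then kingdom, then taxon group) -- an unresolved homonym
#' abstains and is flagged `"Homonym in GBIF"` with backbone fields left
#' absent; (3) without an exact hit, a fuzzy lookup is tried and its sole
#' candidate accepted only at confidence 100; (4) otherwise the name is
#' `MISSING` and kept verbatim. On success the higher taxonomy is
#' retrieved and a taxa group assigned.
#'
#' @param verbatim non-empty taxon name as supplied by the source.
#' @param backbone a `taxonomy_backbone`.
#' @param hints optional list with elements `author`, `kingdom`, `group`.
#' @param group_rules taxa-group rule table (see [default_taxa_group_rules()]).
#' @return one-row tibble (a TaxonMatch).
#' @export
match_taxon <- function(verbatim, backbone, hints = list(),
                        group_rules = default_taxa_group_rules()) {
  stopifnot(is.character(verbatim), length(verbatim) == 1, !is.na(verbatim), nzchar(verbatim))
  hits <- lookup_exact(backbone, verbatim)
  if (nrow(hits) >= 1) {
    if (nrow(hits) > 1) {
      res <- resolve_homonym(hits, hints)
      if (is.null(res)) {
        out <- empty_match(verbatim)
        out$note <- "Homonym in GBIF"
        return(out)
      }
      hits <- res
    }
    return(finish_match(verbatim, hits, "EXACT", backbone, group_rules))
  }
  fz <- lookup_fuzzy(backbone, verbatim)
  fz <- fz[fz$confidence == 100, , drop = FALSE]
  if (nrow(fz) == 1) {
    return(finish_match(verbatim, fz[BACKBONE_COLS], "FUZZY", backbone, group_rules))
  }
  empty_match(verbatim)
}

# Complete a match from a single backbone entry: synonym resolution,
# higher taxonomy, notes, taxa group.
finish_match <- function(verbatim, entry, match_type, backbone, group_rules) {
  note <- NA_character_
  status_synonym <- NA_character_
  if (entry$status %in% c("SYNONYM")) {
    accepted <- resolve_key(backbone, entry$accepted_usage_key)
    status_synonym <- accepted$status
    status <- "SYNONYM"
    # how many distinct accepted names does this synonym point at?
    sibs <- lookup_exact(backbone, entry$canonical_name)
    sib_syn <- sibs[sibs$status == "SYNONYM", , drop = FALSE]
    if (length(unique(sib_syn$accepted_usage_key)) > 1) {
      note <- "Multiple accepted names for synonym in GBIF"
    } else if (nrow(sib_syn) > 1) {
      note <- "Multiple synonyms in GBIF"
    } else {
      note <- "Accepted name found on GBIF"
    }
    final <- accepted
  } else {
    status <- "ACCEPTED"
    final <- entry
  }
  higher <- final[, c("species", "genus", "family", "order", "class", "phylum", "kingdom")]
  tibble::tibble(
    verbatim_name = verbatim,
    taxon = final$canonical_name,
    scientific_name = final$scientific_name,
    status = status,
    status_synonym = status_synonym,
    match_type = match_type,
    rank = final$rank,
    usage_key = final$usage_key,
    note = note,
    species = higher$species, genus = higher$genus, family = higher$family,
    order = higher$order, class = higher$class, phylum = higher$phylum,
    kingdom = higher$kingdom,
    taxa_group = assign_taxa_group(higher, group_rules)
  )
}

#' Resolve homonym candidates with source hints
#'
#' Identical names used for different taxa are disambiguated with
#' information from the original dataset, applied in order: author name,
#' kingdom, taxon group. Each available hint discards non-conforming
#' candidates; a unique survivor wins. Zero or several survivors mean the
#' homonym stays unresolved (`NULL`): abstaining is preferred over
#' guessing.
#'
#' @param candidates tibble of backbone entries sharing a canonical name.
#' @param hints list with optional `author`, `kingdom`, `group` strings.
#' @param group_rules rule table for evaluating the group hint.
#' @return a one-row tibble, or `NULL` when unresolved.
#' @export
resolve_homonym <- function(candidates, hints = list(),
                            group_rules = default_taxa_group_rules()) {
  surv <- candidates
  has <- function(h) !is.null(h) && length(h) == 1 && !is.na(h) && nzchar(h)
  conforming <- list(
    author = function(s) normalize_term(s$authorship) == normalize_term(hints$author),
    kingdom = function(s) normalize_term(s$kingdom) == normalize_term(hints$kingdom),
    group = function(s) {
      grp <- vapply(seq_len(nrow(s)), function(i)
        assign_taxa_group(s[i, ], group_rules) %||% NA_character_, character(1))
      !is.na(grp) & normalize_term(grp) == normalize_term(hints$group)
    }
  )
  for (h in c("author", "kingdom", "group")) {
    if (!has(hints[[h]])) next
    surv <- surv[conforming[[h]](surv), , drop = FALSE]
    if (nrow(surv) <= 1) break
  }
  if (nrow(surv) == 1) surv else NULL
}

#' Strip authority and date from a scientific name
#'
#' Keeps the genus, epithets and infraspecific markers (`var.`, `subsp.`,
#' `f.`, hybrid sign); removes authorship tokens (capitalized words,
#' parenthesized authors, years). For names present in a backbone the
#' result equals the backbone's canonical name.
#'
#' @param scientific_name character vector.
#' @return character vector of canonical names.
#' @export
#' @examples
#' strip_authority("Lonchura malacca (Linnaeus, 1766)")
strip_authority <- function(scientific_name) {
  vapply(as.character(scientific_name), function(s) {
    if (is.na(s)) return(NA_character_)
    s <- stringr::str_squish(s)
    # cut at a parenthesized author immediately
    s <- stringr::str_remove(s, "\\s*\\(.*$")
    tokens <- stringr::str_split_1(s, "\\s+")
    if (length(tokens) == 0) return(s)
    keep <- tokens[1]
    markers <- c("var.", "subsp.", "ssp.", "f.", "forma", "×", "x")
    for (tk in tokens[-1]) {
      if (tk %in% markers || stringr::str_detect(tk, "^[a-z×][a-z-]*$")) {
        keep <- c(keep, tk)
      } else break
    }
    paste(keep, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

#' Default taxa-group rule table
#'
#' Ordered (rank, value, group) rules mapping higher taxonomy to the 20
#' taxa-group labels used for biogeographic summaries (Birds, Mammals,
#' Vascular plants, ...). First matching rule wins; the table is ordinary
#' data and can be edited or replaced by the user (several groups, e.g.
#' algae, are ecological rather than monophyletic). A taxonomy matching no
#' rule gets no group.
#'
#' @return tibble with columns `rank`, `value`, `group`.
#' @export
default_taxa_group_rules <- function() {
  tibble::tribble(
    ~rank,     ~value,              ~group,
    "class",   "Amphibia",          "Amphibians",
    "class",   "Aves",              "Birds",
    "class",   "Mammalia",          "Mammals",
    "class",   "Reptilia",          "Reptiles",
    "class",   "Squamata",          "Reptiles",
    "class",   "Testudines",        "Reptiles",
    "class",   "Crocodylia",        "Reptiles",
    "class",   "Actinopterygii",    "Fishes",
    "class",   "Elasmobranchii",    "Fishes",
    "class",   "Holocephali",       "Fishes",
    "class",   "Sarcopterygii",     "Fishes",
    "class",   "Myxini",            "Fishes",
    "class",   "Petromyzonti",      "Fishes",
    "class",   "Insecta",           "Insects",
    "class",   "Arachnida",         "Arachnids",
    "class",   "Malacostraca",      "Crustaceans",
    "class",   "Branchiopoda",      "Crustaceans",
    "class",   "Maxillopoda",       "Crustaceans",
    "class",   "Copepoda",          "Crustaceans",
    "class",   "Ostracoda",         "Crustaceans",
    "class",   "Thecostraca",       "Crustaceans",
    "class",   "Hexanauplia",       "Crustaceans",
    "phylum",  "Arthropoda",        "Other arthropods",
    "phylum",  "Mollusca",          "Molluscs",
    "phylum",  "Annelida",          "Annelids",
    "phylum",  "Nematoda",          "nematodes, platyhelminthes and other worms",
    "phylum",  "Platyhelminthes",   "nematodes, platyhelminthes and other worms",
    "phylum",  "Nemertea",          "nematodes, platyhelminthes and other worms",
    "phylum",  "Acanthocephala",    "nematodes, platyhelminthes and other worms",
    "phylum",  "Bryophyta",         "Bryophytes",
    "phylum",  "Marchantiophyta",   "Bryophytes",
    "phylum",  "Anthocerotophyta",  "Bryophytes",
    "phylum",  "Tracheophyta",      "Vascular plants",
    "phylum",  "Chlorophyta",       "Algae",
    "phylum",  "Charophyta",        "Algae",
    "phylum",  "Rhodophyta",        "Algae",
    "phylum",  "Ochrophyta",        "Algae",
    "phylum",  "Cnidaria",          "Other aquatic animals",
    "phylum",  "Porifera",          "Other aquatic animals",
    "phylum",  "Echinodermata",     "Other aquatic animals",
    "phylum",  "Ctenophora",        "Other aquatic animals",
    "phylum",  "Bryozoa",           "Other aquatic animals",
    "phylum",  "Brachiopoda",       "Other aquatic animals",
    "phylum",  "Chaetognatha",      "Other aquatic animals",
    "phylum",  "Rotifera",          "Other aquatic animals",
    "kingdom", "Fungi",             "Fungi",
    "kingdom", "Chromista",         "SAR",
    "kingdom", "Bacteria",          "Bacteria and protozoans",
    "kingdom", "Archaea",           "Bacteria and protozoans",
    "kingdom", "Protozoa",          "Bacteria and protozoans",
    "kingdom", "Viruses",           "Viruses"
  )
}

#' Read a taxa-group rule table from a delimited file
#' @param path csv with columns `rank`, `value`, `group` (order matters).
#' @return rule tibble.
#' @export
read_taxa_group_rules <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  miss <- setdiff(c("rank", "value", "group"), names(tbl))
  if (length(miss)) abort_schema(paste("taxa-group rules: missing column(s)",
                                       paste(miss, collapse = ", ")))
  bad <- setdiff(unique(tbl$rank), c("species", "genus", "family", "order",
                                     "class", "phylum", "kingdom"))
  if (length(bad)) abort_config(paste("taxa-group rules: unknown rank(s)",
                                      paste(bad, collapse = ", ")))
  tbl
}

#' Assign a taxa group from higher taxonomy
#'
#' Applies the ordered rule table: the first rule whose rank's value
#' equals the taxonomy's value (normalized comparison) wins.
#'
#' @param higher one-row data frame (or named list) with elements
#'   `species` ... `kingdom`.
#' @param rules rule tibble, default [default_taxa_group_rules()].
#' @return group label, or `NA` when no rule matches or the taxonomy is
#'   empty (unmatched taxa are excluded from group summaries).
#' @export
assign_taxa_group <- function(higher, rules = default_taxa_group_rules()) {
  bad <- setdiff(unique(rules$rank), c("species", "genus", "family", "order",
                                       "class", "phylum", "kingdom"))
  if (length(bad)) abort_config(paste("taxa-group rules: unknown rank(s)",
                                      paste(bad, collapse = ", ")))
  for (i in seq_len(nrow(rules))) {
    v <- higher[[rules$rank[i]]]
    if (length(v) == 1 && !is.na(v) &&
        normalize_term(v) == normalize_term(rules$value[i])) {
      return(rules$group[i])
    }
  }
  NA_character_
}

#' Match many names and build the taxa table
#'
#' Runs [match_taxon()] once per distinct verbatim name (with that name's
#' hints) and returns the matches keyed by verbatim name. Determinism:
#' output order is by verbatim name, independent of record order.
#'
#' @param records raw-record tibble (hint columns are used when present).
#' @param backbone a `taxonomy_backbone`.
#' @param group_rules taxa-group rule table.
#' @return tibble of TaxonMatch rows, one per distinct verbatim name.
#' @export
match_taxa <- function(records, backbone, group_rules = default_taxa_group_rules()) {
  distinct <- records |>
    dplyr::filter(!is.na(.data$taxon_verbatim), .data$taxon_verbatim != "") |>
    dplyr::group_by(.data$taxon_verbatim) |>
    dplyr::summarise(
      author = first_non_na(.data$author_hint),
      kingdom = first_non_na(.data$kingdom_hint),
      group = first_non_na(.data$group_hint),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$taxon_verbatim)
  purrr::pmap(distinct, function(taxon_verbatim, author, kingdom, group) {
    match_taxon(taxon_verbatim, backbone,
                hints = list(author = author, kingdom = kingdom, group = group),
                group_rules = group_rules)
  }) |> dplyr::bind_rows()
}

# Deterministic hint selection: independent of record order.
first_non_na <- function(x) {
  x <- sort(x[!is.na(x) & x != ""], method = "radix")
  if (length(x)) x[1] else NA_character_
}

#' Build the taxa output table from matches
#'
#' One entry per distinct verbatim name: the original name is preserved
#' under `verbatimTaxonRank` (the published schema stores the
#' original-source name under that header), `taxon` holds the accepted
#' canonical name (or the verbatim name when unmatched), and the backbone
#' fields fill the `GBIF*` columns. `taxonID` is assigned later by the
#' integrator ([assign_ids()]).
#'
#' @param matches tibble from [match_taxa()].
#' @return tibble in the taxa-table schema (without `taxonID`).
#' @export
build_taxa_list <- function(matches) {
  matches |>
    dplyr::transmute(
      scientificName = .data$scientific_name,
      verbatimTaxonRank = .data$verbatim_name,
      taxon = .data$taxon,
      GBIFstatus = .data$status,
      GBIFstatus_Synonym = .data$status_synonym,
      GBIFmatchtype = .data$match_type,
      GBIFtaxonRank = .data$rank,
      GBIFusageKey = .data$usage_key,
      GBIFnote = .data$note,
      species = .data$species, genus = .data$genus, family = .data$family,
      order = .data$order, class = .data$class, phylum = .data$phylum,
      kingdom = .data$kingdom,
      taxaGroup = .data$taxa_group
    ) |>
    dplyr::arrange(.data$taxon, .data$verbatimTaxonRank)
}
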