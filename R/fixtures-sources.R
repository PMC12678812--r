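# Source-file generation and the ground-truth ledger. Each source file is
# rendered in its own dialect from an intent table that records, for every
# row, the standardized values the pipeline is expected to recover. The
# ledger is computed from those intents with the naive reference merge and
# plain base-R counting -- never by running the production pipeline.

#' Generate the fixture source datasets, configs and ground-truth ledger
#'
#' Emits up to five sources in distinct dialects (in order):
#' \itemize{
#'   \item `CHK` -- mixed-scope checklist with vocabulary variants, hint
#'     columns and every planted anomaly (synonym and homonym citations, a
#'     misspelling, an unknown name, an unmatched location, an unmatched
#'     establishment term, an unmatched pathway term, an unparseable date,
#'     merge-rule pairs and duplicates);
#'   \item `BIN` -- native checklist with binary-coded establishment,
#'     keep/drop filter columns and subdivision-level records;
#'   \item `MCOL` -- alien checklist with locations split across island /
#'     country columns (finest first) and range-style dates;
#'   \item `RNG` -- range-map source: WKT polygons with origin codes,
#'     converted to checklist records by overlay;
#'   \item `ANT` -- alien checklist filtered on an establishment flag and
#'     restricted to a companion taxon list.
#' }
#'
#' @param spec a [fixture_spec()].
#' @param backbone result of [generate_backbone()].
#' @param locations result of [generate_locations()].
#' @param dir output directory.
#' @return list with `config_path` (sources YAML), `run_config_path`,
#'   `ledger` (expected records / taxa / unmatched reports / summary) and
#'   `intents`.
#' @export
generate_sources <- function(spec, backbone, locations, dir) {
  dir.create(file.path(dir, "sources"), recursive = TRUE, showWarnings = FALSE)
  withr::with_seed(spec$seed + 2L, {
    man <- backbone$manifest
    acc <- backbone$accepted
    trans <- locations$translation
    n <- spec$n_true_taxa
    loc_names <- trans$location
    nloc <- length(loc_names)
    Lix <- function(i) loc_names[(i - 1L) %% nloc + 1L]

    hom_idx <- man$target_idx[man$kind == "homonym"]
    plain_idx <- setdiff(seq_len(n), hom_idx)
    specials <- plain_idx[seq_len(min(13, length(plain_idx)))]
    pA <- acc$canonical_name[specials[1]]; pB <- acc$canonical_name[specials[2]]
    pC <- acc$canonical_name[specials[3]]; pD <- acc$canonical_name[specials[4]]
    pE <- acc$canonical_name[specials[5]]; pF <- acc$canonical_name[specials[6]]
    pG <- acc$canonical_name[specials[7]]; pH <- acc$canonical_name[specials[8]]
    rB <- acc$canonical_name[specials[9]]; rC <- acc$canonical_name[specials[10]]
    rD <- acc$canonical_name[specials[11]]; rE <- acc$canonical_name[specials[12]]
    base_pool <- acc$canonical_name[plain_idx]

    syn_row <- man[man$kind == "synonym", ][1, ]
    hom_rows <- man[man$kind == "homonym", ]
    mis_row <- man[man$kind == "misspelling", ][1, ]
    unk_row <- man[man$kind == "unknown", ][1, ]

    # habitat is a taxon-level trait: assign once per taxon
    hab_taxa <- sample(acc$canonical_name, round(0.4 * n))
    hab_map <- setNames(
      lapply(hab_taxa, function(t) sort(sample(names(VARIANTS$habitat),
                                               sample(1:2, 1)))),
      hab_taxa)
    habitat_of <- function(taxon) {
      h <- hab_map[[taxon]]
      if (is.null(h)) NA_character_ else paste(h, collapse = SEP)
    }

    # place-name rendering: raw text written to the file + expected location
    place_options <- local({
      opts <- tibble::tibble(raw = trans$location, expected = trans$location)
      alts <- trans[trans$alternatives != "", ]
      if (nrow(alts)) opts <- dplyr::bind_rows(opts, tibble::tibble(
        raw = alts$alternatives, expected = alts$location))
      subs <- trans[trans$subdivisions != "", ]
      if (nrow(subs)) {
        for (i in seq_len(nrow(subs))) {
          for (s in split_composite(subs$subdivisions[i])) {
            opts <- dplyr::add_row(opts, raw = s, expected = subs$location[i])
          }
        }
      }
      opts
    })
    draw_place <- function() place_options[sample(nrow(place_options), 1), ]
    loc_id <- function(nm) trans$locationID[match(nm, trans$location)]

    intents <- list(); files <- list(); cfg <- list()
    add_intent <- function(source, verbatim, exp_loc, em, occ = NA, deg = NA,
                           pw = NA, yr = NA, hab = NA_character_) {
      intents[[length(intents) + 1]] <<- tibble::tibble(
        source_name = source, taxon_verbatim = verbatim,
        location = exp_loc, locationID = if (is.na(exp_loc)) NA_integer_ else loc_id(exp_loc),
        establishmentMeans = as.character(em), occurrenceStatus = as.character(occ),
        degreeOfEstablishment = as.character(deg), pathway = as.character(pw),
        habitat = as.character(hab), eventDate = as.integer(yr))
    }

    # ---------------- CHK: mixed-scope checklist --------------------------
    chk <- tibble::tibble(species = character(0), area = character(0),
                          status = character(0), occ = character(0),
                          degree = character(0), pathway = character(0),
                          habitat = character(0), first_record = character(0),
                          author = character(0), kingdom = character(0))
    chk_row <- function(species, area, status, occ = "", degree = "",
                        pathway = "", habitat = "", first_record = "",
                        author = "", kingdom = "") {
      chk <<- dplyr::add_row(chk, species = species, area = area, status = status,
                             occ = occ, degree = degree, pathway = pathway,
                             habitat = habitat, first_record = first_record,
                             author = author, kingdom = kingdom)
    }
    chk_habitat_raw <- function(taxon) {
      h <- hab_map[[taxon]]
      if (is.null(h)) "" else paste(vapply(h, function(t) pick_variant("habitat", t), ""),
                                    collapse = "; ")
    }
    for (i in seq_len(22)) {
      taxon <- sample(base_pool, 1)
      pl <- draw_place()
      em <- sample(c("native", "introduced", "uncertain"), 1, prob = c(.35, .5, .15))
      occ <- if (stats::runif(1) < 0.6) sample(c("present", "absent"), 1, prob = c(.8, .2)) else NA
      deg <- if (em == "introduced" && stats::runif(1) < 0.5)
        sample(names(VARIANTS$degree), 1) else NA
      pw <- if (em == "introduced" && stats::runif(1) < 0.3)
        sample(names(VARIANTS$pathway), 1) else NA
      dt <- if (stats::runif(1) < 0.5) render_date(sample(1850:2015, 1)) else NULL
      chk_row(taxon, pl$raw, pick_variant("establishment", em),
              occ = if (is.na(occ)) "" else pick_variant("occurrence", occ),
              degree = if (is.na(deg)) "" else pick_variant("degree", deg),
              pathway = if (is.na(pw)) "" else sample(VARIANTS$pathway[[pw]], 1),
              habitat = chk_habitat_raw(taxon),
              first_record = if (is.null(dt)) "" else dt$raw)
      add_intent("CHK", taxon, pl$expected, em, occ = occ, deg = deg, pw = pw,
                 yr = if (is.null(dt)) NA else dt$year, hab = habitat_of(taxon))
    }
    planted_unmatched <- list()
    plant_term <- function(field, verbatim) {
      planted_unmatched[[length(planted_unmatched) + 1]] <<-
        tibble::tibble(field = field, source_name = "CHK", verbatim = verbatim,
                       count = 1L)
    }
    if (!is.na(syn_row$verbatim[1])) {
      chk_row(syn_row$verbatim, Lix(2), "introduced", first_record = "1930")
      add_intent("CHK", syn_row$verbatim, Lix(2), "introduced", yr = 1930)
    }
    if (nrow(hom_rows) >= 1) {
      chk_row(hom_rows$verbatim[1], Lix(3), "introduced",
              kingdom = hom_rows$target_kingdom[1])
      add_intent("CHK", hom_rows$verbatim[1], Lix(3), "introduced")
    }
    if (nrow(hom_rows) >= 2) {
      chk_row(hom_rows$verbatim[2], Lix(4), "introduced")
      add_intent("CHK", hom_rows$verbatim[2], Lix(4), "introduced")
    }
    if (!is.na(mis_row$verbatim[1])) {
      chk_row(mis_row$verbatim, Lix(9), "introduced")
      add_intent("CHK", mis_row$verbatim, Lix(9), "introduced")
    }
    chk_row(unk_row$verbatim, Lix(5), "introduced")
    add_intent("CHK", unk_row$verbatim, Lix(5), "introduced")
    # unmatched location -> exclusion
    chk_row(pE, "Atlantis", "introduced")
    add_intent("CHK", pE, NA, "introduced")
    # unmatched establishment term -> exclusion
    chk_row(pF, Lix(6), "weird-status")
    add_intent("CHK", pF, Lix(6), NA)
    plant_term("establishmentMeans", "weird-status")
    # unmatched pathway term -> field absent, record survives
    chk_row(pG, Lix(7), "introduced", pathway = "ballast-magic")
    add_intent("CHK", pG, Lix(7), "introduced")
    plant_term("pathway", "ballast-magic")
    # unparseable date
    chk_row(pH, Lix(8), "introduced", first_record = "sometime")
    add_intent("CHK", pH, Lix(8), "introduced")
    plant_term("eventDate", "sometime")
    # merge-rule plants
    chk_row(pA, Lix(3), "introduced", occ = "present", first_record = "1950")
    add_intent("CHK", pA, Lix(3), "introduced", occ = "present", yr = 1950)
    chk_row(pB, Lix(4), "cryptogenic")
    add_intent("CHK", pB, Lix(4), "uncertain")
    chk_row(pC, Lix(5), "Native")
    add_intent("CHK", pC, Lix(5), "native")
    chk_row(pD, Lix(6), "introduced", occ = "present", first_record = "1903")
    add_intent("CHK", pD, Lix(6), "introduced", occ = "present", yr = 1903)
    chk_row(pD, Lix(6), "alien", occ = "extirpated", first_record = "1950")
    add_intent("CHK", pD, Lix(6), "introduced", occ = "absent", yr = 1950)

    files$CHK <- file.path(dir, "sources", "chk.csv")
    readr::write_csv(chk, files$CHK, na = "", progress = FALSE)
    cfg$CHK <- list(
      path = "sources/chk.csv", scope = "mixed",
      citation = "Example Checklist Consortium (2023) A mixed checklist of fixture taxa.",
      column_map = list(taxon = "species", location = "area",
                        establishment = "status", occurrence = "occ",
                        degree = "degree", pathway = "pathway",
                        habitat = "habitat", event_date = "first_record",
                        author = "author", kingdom = "kingdom"))

    # ---------------- BIN: binary-coded native checklist ------------------
    if (spec$n_sources >= 2) {
      bin <- tibble::tibble(taxon_name = character(0), region = character(0),
                            introduced = character(0), location_doubtful = character(0))
      for (i in seq_len(10)) {
        taxon <- sample(base_pool, 1)
        pl <- draw_place()
        bin <- dplyr::add_row(bin, taxon_name = taxon, region = pl$raw,
                              introduced = "0", location_doubtful = "0")
        add_intent("BIN", taxon, pl$expected, "native")
      }
      for (i in seq_len(3)) {   # alien-flagged rows are filtered out
        bin <- dplyr::add_row(bin, taxon_name = sample(base_pool, 1),
                              region = Lix(i), introduced = "1",
                              location_doubtful = "0")
      }
      for (i in seq_len(2)) {   # doubtful rows are filtered out
        bin <- dplyr::add_row(bin, taxon_name = sample(base_pool, 1),
                              region = Lix(i), introduced = "0",
                              location_doubtful = "1")
      }
      files$BIN <- file.path(dir, "sources", "bin.tsv")
      readr::write_tsv(bin, files$BIN, na = "", progress = FALSE)
      cfg$BIN <- list(
        path = "sources/bin.tsv", scope = "native", delim = "\t",
        citation = "Fixture Plant Compendium (2024) Native ranges with binary coding.",
        column_map = list(taxon = "taxon_name", location = "region",
                          establishment = "introduced"),
        keep_rules = list(introduced = list("0")),
        drop_rules = list(location_doubtful = list("1")),
        establishment_encoding = list("0" = "native", "1" = "introduced"))
    }

    # ---------------- MCOL: multi-column-location alien checklist ---------
    if (spec$n_sources >= 3) {
      mcol <- tibble::tibble(sp = character(0), island = character(0),
                             country = character(0), degree = character(0),
                             established_when = character(0))
      mcol_row <- function(sp, island, country, degree = "", when = "") {
        mcol <<- dplyr::add_row(mcol, sp = sp, island = island, country = country,
                                degree = degree, established_when = when)
      }
      fine_options <- place_options[!place_options$raw %in% trans$location, ]
      for (i in seq_len(12)) {
        taxon <- sample(base_pool, 1)
        deg <- if (stats::runif(1) < 0.4) sample(names(VARIANTS$degree), 1) else NA
        dt <- if (stats::runif(1) < 0.6) render_date(sample(1800:2010, 1)) else NULL
        if (stats::runif(1) < 0.5 && nrow(fine_options)) {
          pl <- fine_options[sample(nrow(fine_options), 1), ]
          mcol_row(taxon, pl$raw, sample(trans$location, 1),
                   degree = if (is.na(deg)) "" else pick_variant("degree", deg),
                   when = if (is.null(dt)) "" else dt$raw)
          exp_loc <- pl$expected
        } else {
          exp_loc <- sample(trans$location, 1)
          mcol_row(taxon, "", exp_loc,
                   degree = if (is.na(deg)) "" else pick_variant("degree", deg),
                   when = if (is.null(dt)) "" else dt$raw)
        }
        add_intent("MCOL", taxon, exp_loc, "introduced", deg = deg,
                   yr = if (is.null(dt)) NA else dt$year)
      }
      mcol_row(pB, "", Lix(4))
      add_intent("MCOL", pB, Lix(4), "introduced")
      mcol_row(pC, "", Lix(5))
      add_intent("MCOL", pC, Lix(5), "introduced")
      mcol_row(pD, "", Lix(6), when = "1950")
      add_intent("MCOL", pD, Lix(6), "introduced", yr = 1950)
      files$MCOL <- file.path(dir, "sources", "mcol.csv")
      readr::write_csv(mcol, files$MCOL, na = "", progress = FALSE)
      cfg$MCOL <- list(
        path = "sources/mcol.csv", scope = "alien",
        citation = "Fixture Atlas of Naturalized Taxa (2022) Multi-column distributions.",
        column_map = list(taxon = "sp", location = list("island", "country"),
                          degree = "degree", event_date = "established_when"))
    }

    # ---------------- RNG: range-map source -------------------------------
    if (spec$n_sources >= 4) {
      k <- as.integer(sqrt(spec$n_locations))
      rect_wkt <- function(x0, y0, x1, y1) {
        format_wkt(rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0)))
      }
      # expected overlapping grid squares by interval arithmetic
      rect_locs <- function(x0, y0, x1, y1) {
        hit <- which(locations$col < x1 & locations$col + 1 > x0 &
                       locations$row < y1 & locations$row + 1 > y0)
        loc_names[hit]
      }
      feats <- tibble::tibble(taxon_verbatim = character(0), wkt = character(0),
                              origin_code = character(0))
      feat <- function(taxon, x0, y0, x1, y1, origin, expected = TRUE) {
        feats <<- dplyr::add_row(feats, taxon_verbatim = taxon,
                                 wkt = rect_wkt(x0, y0, x1, y1), origin_code = origin)
        if (expected && origin %in% c("native", "reintroduced")) {
          for (lc in rect_locs(x0, y0, x1, y1)) add_intent("RNG", taxon, lc, "native")
        }
      }
      feat(pA, 0.25, 0.25, 0.75, 0.75, "native")
      feat(rB, 0.5, 0.25, 1.5, 0.75, "native")
      feat(rC, 1, 1, 2, 2, "reintroduced")
      feat(rD, 0, min(2.5, k - 0.5), min(3, k), k, "native")
      feat(rE, 0.25, 0.25, 1.75, 0.75, "vagrant")        # origin discarded
      feat(rE, 0.25, 1.25, 0.75, 1.75, "introduced")     # origin discarded
      feat(pA, 0.25, 0.25, 0.5, 0.5, "native", expected = FALSE)  # duplicate
      feats <- dplyr::add_row(feats, taxon_verbatim = rE,
                              wkt = "POLYGON ((0 0, 1 1, 0 0))",
                              origin_code = "native")    # invalid, skipped
      files$RNG <- file.path(dir, "sources", "rng.csv")
      readr::write_csv(feats, files$RNG, na = "", progress = FALSE)
      cfg$RNG <- list(
        path = "sources/rng.csv", type = "range_map", scope = "native",
        citation = "Fixture Range Map Initiative (2024) Expert polygons of native ranges.",
        column_map = list(taxon = "taxon_verbatim", location = "wkt"),
        origin_keep = list("native", "reintroduced"))
    }

    # ---------------- ANT: flag-filtered, list-restricted alien source ----
    if (spec$n_sources >= 5) {
      ant <- tibble::tibble(ant_species = character(0), place = character(0),
                            establishment_flag = character(0))
      ant_taxa <- unique(c(pA, sample(base_pool, 7)))
      off_list <- ant_taxa[length(ant_taxa)]          # not on restriction list
      for (i in seq_along(ant_taxa)) {
        pl <- if (ant_taxa[i] == pA) list(raw = Lix(3), expected = Lix(3)) else draw_place()
        ant <- dplyr::add_row(ant, ant_species = ant_taxa[i], place = pl$raw,
                              establishment_flag = "established outdoors")
        if (ant_taxa[i] != off_list) {
          add_intent("ANT", ant_taxa[i], pl$expected, "introduced")
        }
      }
      for (i in seq_len(3)) {   # indoor records are filtered out
        ant <- dplyr::add_row(ant, ant_species = sample(ant_taxa, 1),
                              place = Lix(i), establishment_flag = "indoors only")
      }
      list_path <- file.path(dir, "sources", "ant_list.txt")
      writeLines(setdiff(ant_taxa, off_list), list_path)
      files$ANT <- file.path(dir, "sources", "ant.csv")
      readr::write_csv(ant, files$ANT, na = "", progress = FALSE)
      cfg$ANT <- list(
        path = "sources/ant.csv", scope = "alien",
        citation = "Fixture Myrmecology Group (2023) Establishment-flagged records.",
        column_map = list(taxon = "ant_species", location = "place"),
        keep_rules = list(establishment_flag = list("established outdoors")),
        restrict_to_list = "sources/ant_list.txt")
    }

    intents <- dplyr::bind_rows(intents)
    config_path <- file.path(dir, "sources.yaml")
    yaml::write_yaml(list(sources = cfg), config_path)
    run_config_path <- file.path(dir, "run.yaml")
    yaml::write_yaml(list(
      sources = "sources.yaml",
      locations = list(polygons = basename(locations$polygon_path),
                       translation = basename(locations$translation_path)),
      backbone = list(mode = "local", path = basename(backbone$path)),
      output_dir = "output"
    ), run_config_path)

    citations <- vapply(cfg, function(s) s$citation, "")
    names(citations) <- names(cfg)
    ledger <- build_ledger(intents, man, acc, planted_unmatched, citations)
    list(config_path = config_path, run_config_path = run_config_path,
         files = files, intents = intents, ledger = ledger)
  })
}

# Expected outputs from the intent table: naive reference merge for the
# records, manifest-driven construction for the taxa list, plain counting
# for the summary.
build_ledger <- function(intents, manifest, accepted, planted_unmatched, citations) {
  # expected match outcome per distinct verbatim name
  kinds <- manifest[match(intents$taxon_verbatim, manifest$verbatim), ]
  hinted <- unique(intents$taxon_verbatim[
    intents$source_name == "CHK" & !is.na(kinds$kind) & kinds$kind == "homonym"])
  # the first homonym citation carries a kingdom hint (by construction);
  # hint availability is per distinct name, so resolve iff it is the first
  hom_names <- manifest$verbatim[manifest$kind == "homonym"]
  resolved_homonyms <- intersect(hom_names[1], hinted)

  expected_taxon <- function(verbatim) {
    m <- manifest[manifest$verbatim == verbatim, ]
    if (nrow(m) == 0) return(verbatim)
    if (m$kind[1] %in% c("accepted", "synonym", "misspelling")) return(m$target_canonical[1])
    if (m$kind[1] == "homonym" && verbatim %in% resolved_homonyms) return(m$target_canonical[1])
    verbatim
  }

  recs <- intents
  recs$taxon <- vapply(recs$taxon_verbatim, expected_taxon, "")
  merged <- merge_records_naive(recs, citations)

  verbatims <- sort(unique(intents$taxon_verbatim))
  taxa <- dplyr::bind_rows(lapply(verbatims, function(v) {
    m <- manifest[manifest$verbatim == v, ]
    kind <- if (nrow(m)) m$kind[1] else "unknown"
    missing_row <- function(note = NA_character_) tibble::tibble(
      scientificName = NA_character_, verbatimTaxonRank = v, taxon = v,
      GBIFstatus = "MISSING", GBIFstatus_Synonym = NA_character_,
      GBIFmatchtype = NA_character_, GBIFtaxonRank = NA_character_,
      GBIFusageKey = NA_integer_, GBIFnote = note,
      species = NA_character_, genus = NA_character_, family = NA_character_,
      order = NA_character_, class = NA_character_, phylum = NA_character_,
      kingdom = NA_character_, taxaGroup = NA_character_)
    if (kind == "unknown") return(missing_row())
    if (kind == "homonym" && !v %in% resolved_homonyms) {
      return(missing_row(note = "Homonym in GBIF"))
    }
    a <- accepted[m$target_idx[1], ]
    tibble::tibble(
      scientificName = a$scientific_name, verbatimTaxonRank = v,
      taxon = a$canonical_name,
      GBIFstatus = if (kind == "synonym") "SYNONYM" else "ACCEPTED",
      GBIFstatus_Synonym = if (kind == "synonym") "ACCEPTED" else NA_character_,
      GBIFmatchtype = if (kind == "misspelling") "FUZZY" else "EXACT",
      GBIFtaxonRank = "SPECIES", GBIFusageKey = a$usage_key,
      GBIFnote = if (kind == "synonym") "Accepted name found on GBIF" else NA_character_,
      species = a$species, genus = a$genus, family = a$family, order = a$order,
      class = a$class, phylum = a$phylum, kingdom = a$kingdom,
      taxaGroup = manifest$target_group[manifest$verbatim == v][1])
  }))
  taxa <- taxa[order(taxa$taxon, taxa$verbatimTaxonRank, method = "radix"), ]
  taxa$taxonID <- seq_len(nrow(taxa))
  canonical_id <- taxa$taxonID[!duplicated(taxa$taxon)]
  names(canonical_id) <- taxa$taxon[!duplicated(taxa$taxon)]
  merged$taxonID <- unname(canonical_id[merged$taxon])
  expected_exclusions <- attr(merged, "exclusions")
  merged <- merged[, RECORD_TABLE_COLS]
  attr(merged, "exclusions") <- NULL
  taxa <- taxa[, TAXA_TABLE_COLS]

  unmatched_terms <- dplyr::bind_rows(planted_unmatched)
  em <- merged$establishmentMeans
  nrec <- nrow(merged)
  pct <- function(x) floor(1000 * x / nrec + 0.5) / 10
  summary <- list(
    n_records = nrec,
    n_taxa_total = length(unique(taxa$taxon)),
    n_taxa_alien_distribution = length(unique(merged$taxon[em != "native"])),
    n_taxa_native_distribution = length(unique(merged$taxon[em == "native"])),
    n_locations = length(unique(merged$locationID)),
    n_introduced = sum(em == "introduced"),
    pct_introduced = pct(sum(em == "introduced")),
    n_native = sum(em == "native"),
    pct_native = pct(sum(em == "native")),
    n_introduced_uncertain = sum(em == "introduced; uncertain"),
    n_uncertain = sum(em == "uncertain"),
    n_event_date = sum(!is.na(merged$eventDate)),
    n_taxa_matched_backbone = length(unique(taxa$taxon[taxa$GBIFstatus != "MISSING"]))
  )
  list(records = tibble::as_tibble(merged), taxa = tibble::as_tibble(taxa),
       unmatched_terms = unmatched_terms,
       exclusions = tibble::as_tibble(expected_exclusions),
       summary = summary)
}

#' Generate a complete fixture set
#'
#' Runs the three sub-generators into one directory and returns everything
#' needed to run and check the pipeline: the run-configuration path and
#' the ground-truth ledger.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory.
#' @return list with `spec`, `dir`, `backbone`, `locations`, `sources`
#'   (including `$ledger` and `$run_config_path`).
#' @export
generate_fixture_set <- function(spec = fixture_spec(), dir = tempfile("fixture")) {
  backbone <- generate_backbone(spec, dir)
  locations <- generate_locations(spec, dir)
  sources <- generate_sources(spec, backbone, locations, dir)
  list(spec = spec, dir = dir, backbone = backbone, locations = locations,
       sources = sources)
}
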