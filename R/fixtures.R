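# Synthetic fixture generator: a fixture backbone, a grid location layer,
# and multi-dialect source datasets with a ground-truth ledger, so the
# entire pipeline is exercisable with no downloads. Taxon names are
# pronounceable synthetic binomials (never real names). One seed threads
# every sub-generator; identical seeds give byte-identical files.

SYLLABLES <- c("ba", "ce", "di", "fo", "gu", "ha", "ki", "lo", "mu", "ne",
               "po", "ra", "su", "ta", "ve", "wi", "za", "ru", "mi", "sa")

# Higher-taxonomy pools and the taxa group each implies.
TAXO_POOL <- tibble::tribble(
  ~kingdom,   ~phylum,         ~class,            ~group,
  "Animalia", "Chordata",      "Aves",            "Birds",
  "Animalia", "Chordata",      "Mammalia",        "Mammals",
  "Animalia", "Chordata",      "Actinopterygii",  "Fishes",
  "Animalia", "Arthropoda",    "Insecta",         "Insects",
  "Animalia", "Mollusca",      "Gastropoda",      "Molluscs",
  "Plantae",  "Tracheophyta",  "Magnoliopsida",   "Vascular plants",
  "Fungi",    "Basidiomycota", "Agaricomycetes",  "Fungi"
)

#' Specify a synthetic fixture set
#'
#' The defaults define the standard test conditions: about 60 true taxa
#' with planted synonyms, homonyms and misspellings, a 3 x 3 grid of
#' square locations with subdivisions and alternative spellings, and five
#' sources in distinct dialects (mixed-scope checklist, binary-coded
#' native checklist at subdivision level, multi-column-location alien
#' checklist, polygon range maps with origin codes, flag-filtered alien
#' checklist with a taxon restriction list).
#'
#' @param seed integer seed threading all sub-generators.
#' @param n_true_taxa number of accepted taxa in the fixture backbone.
#' @param synonym_fraction,homonym_fraction,misspelling_fraction
#'   proportions of true taxa given a synonym entry, an across-kingdom
#'   homonym partner, or a planted one-edit misspelling; their sum must
#'   not exceed 1.
#' @param n_locations number of grid locations (perfect square).
#' @param n_sources number of source datasets (1 to 5, dialects in fixed
#'   order).
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 20260101, n_true_taxa = 60,
                         synonym_fraction = 0.15, homonym_fraction = 0.05,
                         misspelling_fraction = 0.10,
                         n_locations = 9, n_sources = 5) {
  if (synonym_fraction + homonym_fraction + misspelling_fraction > 1) {
    abort_config("fixture_spec: synonym + homonym + misspelling fractions must sum to <= 1")
  }
  k <- sqrt(n_locations)
  if (k != floor(k)) abort_config("fixture_spec: n_locations must be a perfect square")
  if (n_sources < 1 || n_sources > 5) abort_config("fixture_spec: n_sources must be 1..5")
  structure(list(seed = as.integer(seed), n_true_taxa = as.integer(n_true_taxa),
                 synonym_fraction = synonym_fraction,
                 homonym_fraction = homonym_fraction,
                 misspelling_fraction = misspelling_fraction,
                 n_locations = as.integer(n_locations),
                 n_sources = as.integer(n_sources)),
            class = "fixture_spec")
}

rand_word <- function(n_syl) paste(sample(SYLLABLES, n_syl, replace = TRUE), collapse = "")

rand_binomial <- function() {
  paste(stringr::str_to_title(rand_word(sample(2:3, 1))), rand_word(sample(2:3, 1)))
}

# Draw names pairwise-distant in edit distance (>= 4), so one-edit
# misspellings are uniquely attributable to their target.
draw_distinct_names <- function(n, taken = character(0), min_dist = 4) {
  out <- character(0)
  pool <- c(taken, out)
  while (length(out) < n) {
    cand <- rand_binomial()
    key <- normalize_term(cand)
    if (length(pool) == 0 || min(osa_distance(key, normalize_term(pool))) >= min_dist) {
      out <- c(out, cand); pool <- c(pool, cand)
    }
  }
  out
}

#' Generate the fixture taxonomy backbone
#'
#' Writes `backbone.csv` (the local-backbone format) containing accepted
#' names, synonym rows pointing at accepted keys, and homonym pairs across
#' kingdoms, and returns a manifest of every name a source may cite with
#' its expected match outcome (including planted misspellings and an
#' unknown name absent from the backbone).
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory.
#' @return list with `table` (backbone tibble), `manifest` (name
#'   manifest), `path`.
#' @export
generate_backbone <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  withr::with_seed(spec$seed, {
    n <- spec$n_true_taxa
    ns <- round(spec$synonym_fraction * n)
    nh <- round(spec$homonym_fraction * n)
    nm <- round(spec$misspelling_fraction * n)
    canon <- draw_distinct_names(n)
    syn_names <- draw_distinct_names(ns, taken = canon)
    unknown <- draw_distinct_names(1, taken = c(canon, syn_names))

    pool_idx <- sample(nrow(TAXO_POOL), n, replace = TRUE)
    genus <- stringr::str_extract(canon, "^\\S+")
    authorship <- sprintf("%s, %d", stringr::str_to_title(vapply(seq_len(n), function(i) rand_word(2), "")),
                          1750 + (seq_len(n) * 7) %% 250)

    accepted <- tibble::tibble(
      usage_key = 1000L + seq_len(n),
      scientific_name = paste(canon, authorship),
      canonical_name = canon,
      authorship = authorship,
      rank = "SPECIES",
      status = "ACCEPTED",
      accepted_usage_key = 1000L + seq_len(n),
      kingdom = TAXO_POOL$kingdom[pool_idx],
      phylum = TAXO_POOL$phylum[pool_idx],
      class = TAXO_POOL$class[pool_idx],
      order = paste0(genus, "ales"),
      family = paste0(genus, "idae"),
      genus = genus,
      species = canon
    )

    syn_idx <- seq_len(ns)                         # taxa owning a synonym
    hom_idx <- ns + seq_len(nh)                    # taxa owning a homonym partner
    mis_idx <- ns + nh + seq_len(nm)               # taxa owning a misspelling

    synonyms <- if (ns > 0) {
      sg <- stringr::str_extract(syn_names, "^\\S+")
      sa <- sprintf("%s, %d", stringr::str_to_title(vapply(seq_len(ns), function(i) rand_word(2), "")),
                    1760 + (seq_len(ns) * 11) %% 240)
      tibble::tibble(
        usage_key = 5000L + syn_idx,
        scientific_name = paste(syn_names, sa),
        canonical_name = syn_names,
        authorship = sa, rank = "SPECIES", status = "SYNONYM",
        accepted_usage_key = 1000L + syn_idx,
        kingdom = accepted$kingdom[syn_idx], phylum = accepted$phylum[syn_idx],
        class = accepted$class[syn_idx], order = accepted$order[syn_idx],
        family = accepted$family[syn_idx], genus = sg,
        species = accepted$species[syn_idx]
      )
    } else accepted[0, ]

    homonyms <- if (nh > 0) {
      alt_pool <- vapply(hom_idx, function(i) {
        cand <- setdiff(seq_len(nrow(TAXO_POOL)),
                        which(TAXO_POOL$kingdom == accepted$kingdom[i]))
        sample(cand, 1)
      }, integer(1))
      ha <- sprintf("%s, %d", stringr::str_to_title(vapply(seq_len(nh), function(i) rand_word(2), "")),
                    1770 + (seq_len(nh) * 13) %% 230)
      tibble::tibble(
        usage_key = 7000L + hom_idx,
        scientific_name = paste(accepted$canonical_name[hom_idx], ha),
        canonical_name = accepted$canonical_name[hom_idx],
        authorship = ha, rank = "SPECIES", status = "ACCEPTED",
        accepted_usage_key = 7000L + hom_idx,
        kingdom = TAXO_POOL$kingdom[alt_pool], phylum = TAXO_POOL$phylum[alt_pool],
        class = TAXO_POOL$class[alt_pool],
        order = accepted$order[hom_idx], family = accepted$family[hom_idx],
        genus = accepted$genus[hom_idx], species = accepted$canonical_name[hom_idx]
      )
    } else accepted[0, ]

    misspell <- function(name) {
      # substitute the final letter of the epithet
      last <- stringr::str_sub(name, -1)
      repl <- if (last == "q") "z" else "q"
      paste0(stringr::str_sub(name, 1, -2), repl)
    }
    mis_verbatim <- vapply(accepted$canonical_name[mis_idx], misspell, "",
                           USE.NAMES = FALSE)

    table <- dplyr::bind_rows(accepted, synonyms, homonyms)
    path <- file.path(dir, "backbone.csv")
    readr::write_csv(table, path, na = "", progress = FALSE)

    expected_group <- function(i) TAXO_POOL$group[pool_idx[i]]
    plain_idx <- setdiff(seq_len(n), hom_idx)  # homonym names are ambiguous
    manifest <- dplyr::bind_rows(
      tibble::tibble(kind = "accepted",
                     verbatim = accepted$canonical_name[plain_idx],
                     target_idx = plain_idx),
      if (ns > 0) tibble::tibble(kind = "synonym", verbatim = syn_names,
                                 target_idx = syn_idx),
      if (nh > 0) tibble::tibble(kind = "homonym",
                                 verbatim = accepted$canonical_name[hom_idx],
                                 target_idx = hom_idx),
      if (nm > 0) tibble::tibble(kind = "misspelling", verbatim = mis_verbatim,
                                 target_idx = mis_idx),
      tibble::tibble(kind = "unknown", verbatim = unknown,
                     target_idx = NA_integer_)
    )
    manifest$target_canonical <- ifelse(is.na(manifest$target_idx), NA,
                                        accepted$canonical_name[manifest$target_idx])
    manifest$target_scientific <- ifelse(is.na(manifest$target_idx), NA,
                                         accepted$scientific_name[manifest$target_idx])
    manifest$target_key <- ifelse(is.na(manifest$target_idx), NA,
                                  accepted$usage_key[manifest$target_idx])
    manifest$target_kingdom <- ifelse(is.na(manifest$target_idx), NA,
                                      accepted$kingdom[manifest$target_idx])
    manifest$target_group <- ifelse(is.na(manifest$target_idx), NA,
                                    vapply(manifest$target_idx, function(i)
                                      if (is.na(i)) NA_character_ else expected_group(i), ""))
    list(table = table, accepted = accepted, manifest = manifest, path = path)
  })
}

#' Generate the fixture location layer
#'
#' A k x k grid of disjoint unit-square locations (WKT polygon table +
#' translation table) with alternative spellings on the first locations,
#' subdivisions on the first two, and two aggregation schemes (`custom`
#' zones by grid column, `realm` by grid row), each of which partitions
#' the location set by construction.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory.
#' @return list with `translation`, `polygon_path`, `translation_path`,
#'   and per-location helper columns (`col`, `row`).
#' @export
generate_locations <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  withr::with_seed(spec$seed + 1L, {
    n <- spec$n_locations; k <- as.integer(sqrt(n))
    names <- stringr::str_to_title(draw_distinct_names(n, min_dist = 3))
    names <- stringr::str_extract(names, "^\\S+")  # single-word place names
    while (anyDuplicated(names)) names[duplicated(names)] <- paste0(names[duplicated(names)], "a")
    col <- (seq_len(n) - 1L) %% k
    row <- (seq_len(n) - 1L) %/% k
    trans <- tibble::tibble(
      location = names,
      locationID = 7L * seq_len(n) + 3L,
      alternatives = ifelse(seq_len(n) <= 3, paste0(names, "ia"), ""),
      subdivisions = dplyr::case_when(
        seq_len(n) == 1 ~ paste0("North ", names, "; South ", names),
        seq_len(n) == 2 ~ paste0("Upper ", names, "; Lower ", names),
        TRUE ~ ""
      ),
      custom = paste0("zone-", col + 1L),
      realm = paste0("realm-", row + 1L)
    )
    polys <- tibble::tibble(
      location = names,
      wkt = vapply(seq_len(n), function(i) format_wkt(square_geom(col[i], row[i])), "")
    )
    polygon_path <- file.path(dir, "locations_polygons.csv")
    translation_path <- file.path(dir, "locations_translation.csv")
    readr::write_csv(polys, polygon_path, na = "", progress = FALSE)
    readr::write_csv(trans, translation_path, na = "", progress = FALSE)
    list(translation = trans, col = col, row = row,
         polygon_path = polygon_path, translation_path = translation_path)
  })
}

#' Generate random convex range-map features
#'
#' Convex hulls of random points snapped to a 0.25-degree lattice over the
#' fixture grid, rejection-sampled so that every positive-area
#' intersection with a grid location has area of at least `min_area`
#' square degrees. Used for overlay/oracle comparisons.
#'
#' @param n number of features.
#' @param seed integer seed.
#' @param extent grid extent in degrees (features are drawn in
#'   `[-0.5, extent + 0.5]`).
#' @param min_area minimal admissible positive intersection area.
#' @return tibble with columns `feature_id`, `wkt`.
#' @export
generate_range_features <- function(n, seed, extent = 3, min_area = 0.02) {
  withr::with_seed(seed, {
    squares <- list()
    for (cx in 0:(extent - 1)) for (cy in 0:(extent - 1)) {
      squares[[length(squares) + 1]] <- square_geom(cx, cy)
    }
    draw_one <- function() {
      repeat {
        m <- cbind(stats::runif(8, -0.5, extent + 0.5),
                   stats::runif(8, -0.5, extent + 0.5))
        m <- round(m * 4) / 4
        h <- grDevices::chull(m)
        if (length(h) < 3) next
        ring <- close_ring(m[h, , drop = FALSE])
        g <- structure(list(list(ring)), class = "adist_geom")
        if (!geom_is_valid(g)) next
        areas <- vapply(squares, function(s) geom_intersection_area(g, s), 0)
        if (all(areas == 0 | areas >= min_area)) return(g)
      }
    }
    tibble::tibble(feature_id = seq_len(n),
                   wkt = vapply(seq_len(n), function(i) format_wkt(draw_one()), ""))
  })
}

# Variant dictionaries: raw spellings that the default vocabularies
# translate back to the wanted canonical term.
VARIANTS <- list(
  establishment = list(native = c("native", "Native", "indigenous"),
                       introduced = c("introduced", "alien", "exotic", "non-native"),
                       uncertain = c("uncertain", "cryptogenic")),
  occurrence = list(present = c("present", "extant"),
                    absent = c("absent", "extirpated")),
  degree = list(established = c("established", "naturalized"),
                reproducing = c("reproducing", "breeding"),
                invasive = c("invasive")),
  pathway = list("escape from confinement" = c("escape", "escape from confinement"),
                 "release in nature" = c("release")),
  habitat = list(freshwater = c("freshwater", "limnic"),
                 marine = c("marine", "sea"),
                 terrestrial = c("terrestrial", "land"),
                 brackish = c("brackish"))
)

pick_variant <- function(kind, canonical) {
  opts <- VARIANTS[[kind]][[canonical]]
  sample(opts, 1)
}

# Render a target year in a random date dialect; returns list(raw, year).
render_date <- function(year) {
  dialect <- sample(c("plain", "even_range", "odd_range", "circa", "iso", "decade"), 1)
  switch(dialect,
    plain = list(raw = as.character(year), year = year),
    even_range = {
      d <- sample(c(2L, 4L, 6L), 1)
      list(raw = sprintf("%d-%d", year - d / 2, year + d / 2), year = year)
    },
    odd_range = list(raw = sprintf("%d-%d", year, year + 1L), year = year),
    circa = list(raw = paste0("c. ", year), year = year),
    iso = list(raw = sprintf("%d-06-15", year), year = year),
    decade = {
      dec <- (year %/% 10L) * 10L
      list(raw = paste0(dec, "s"), year = dec)
    }
  )
}
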