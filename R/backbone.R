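# Taxonomy backbones. The matcher talks to a small interface --
# lookup_exact(), lookup_fuzzy(), resolve() -- with two implementations:
# a local table-backed backbone (delimited text; used in all tests) and a
# cache-backed adapter for the GBIF species-match web service whose
# responses are persisted as JSON lines so runs are reproducible offline.

BACKBONE_COLS <- c(
  "usage_key", "scientific_name", "canonical_name", "authorship", "rank",
  "status", "accepted_usage_key", "kingdom", "phylum", "class", "order",
  "family", "genus", "species"
)

#' Load a local table-backed taxonomy backbone
#'
#' The file is delimited text with columns `usage_key`, `scientific_name`,
#' `canonical_name`, `authorship`, `rank`, `status` (`ACCEPTED`,
#' `SYNONYM`, `DOUBTFUL`), `accepted_usage_key` (self for accepted
#' entries) and the higher taxonomy `kingdom` ... `species`.
#'
#' @param path file path (csv/tsv) or a data frame with those columns.
#' @return a `taxonomy_backbone` object.
#' @export
local_backbone <- function(path) {
  tbl <- if (is.data.frame(path)) tibble::as_tibble(path) else {
    readr::read_csv(path, col_types = readr::cols(.default = "c"),
                    progress = FALSE, show_col_types = FALSE)
  }
  miss <- setdiff(BACKBONE_COLS, names(tbl))
  if (length(miss)) abort_schema(paste("backbone table: missing column(s)",
                                       paste(miss, collapse = ", ")))
  tbl$usage_key <- as.integer(tbl$usage_key)
  tbl$accepted_usage_key <- as.integer(tbl$accepted_usage_key)
  bad <- tbl$status == "ACCEPTED" & tbl$accepted_usage_key != tbl$usage_key
  if (any(bad)) abort_config("backbone: accepted entries must be their own accepted_usage_key")
  orphan <- !tbl$accepted_usage_key %in% tbl$usage_key
  if (any(orphan)) abort_config("backbone: accepted_usage_key not resolvable for some entries")
  tbl$canonical_norm <- normalize_term(tbl$canonical_name)
  tbl$scientific_norm <- normalize_term(tbl$scientific_name)
  structure(list(type = "local", table = tbl), class = "taxonomy_backbone")
}

#' @export
print.taxonomy_backbone <- function(x, ...) {
  n <- if (x$type == "local") nrow(x$table) else length(x$cache)
  cat(sprintf("<taxonomy_backbone: %s, %d entries>\n", x$type, n))
  invisible(x)
}

#' Exact name lookup in a backbone
#'
#' @param backbone a `taxonomy_backbone`.
#' @param name query name (canonical or full scientific name).
#' @return tibble of matching backbone entries (0 or more rows).
#' @export
lookup_exact <- function(backbone, name) {
  key <- normalize_match_name(name)
  if (backbone$type == "local") {
    t <- backbone$table
    t[t$canonical_norm == key | t$scientific_norm == key, BACKBONE_COLS]
  } else {
    gbif_cached_lookup(backbone, name, fuzzy = FALSE)
  }
}

#' Fuzzy name lookup in a backbone
#'
#' For the local backbone, candidates are entries within Damerau-Levenshtein
#' (optimal string alignment) distance 2 of the query's canonical form.
#' Confidence is 100 iff the candidate set is a single entry (by canonical
#' name) at distance <= 1 with no other canonical name within distance 2 --
#' a deterministic rendering of "high-confidence fuzzy match"; anything
#' looser scores 90 and is rejected by the cascade's confidence-100 rule.
#'
#' @param backbone a `taxonomy_backbone`.
#' @param name query name.
#' @return tibble of backbone entries with a `confidence` column.
#' @export
lookup_fuzzy <- function(backbone, name) {
  if (backbone$type != "local") return(gbif_cached_lookup(backbone, name, fuzzy = TRUE))
  key <- normalize_match_name(name)
  t <- backbone$table
  d <- osa_distance(key, t$canonical_norm)
  cand <- t[d <= 2, BACKBONE_COLS]
  if (nrow(cand) == 0) return(cbind(cand, tibble::tibble(confidence = integer(0))))
  dcand <- d[d <= 2]
  n_entries_d1 <- sum(dcand <= 1)
  names2 <- unique(cand$canonical_name)
  conf <- if (n_entries_d1 == 1 && length(names2) == 1) 100L else 90L
  cand$confidence <- ifelse(dcand <= 1, conf, 90L)
  cand
}

#' Resolve a usage key to its backbone entry
#' @param backbone a `taxonomy_backbone`.
#' @param usage_key integer key.
#' @return one-row tibble (error if unknown).
#' @export
resolve_key <- function(backbone, usage_key) {
  if (backbone$type == "local") {
    hit <- backbone$table[backbone$table$usage_key == usage_key, BACKBONE_COLS]
    if (nrow(hit) != 1) abort_config(sprintf("unknown usage key: %s", usage_key))
    hit
  } else {
    abort_config("resolve_key: cached service adapter resolves via its cache entries only")
  }
}

# Matching normal form: hybrid markers stripped, genus capitalization
# neutralized by case-folding, diacritics removed, whitespace collapsed.
normalize_match_name <- function(x) {
  x <- stringr::str_remove_all(as.character(x), "×\\s*|\\bx\\s+(?=[a-z])")
  normalize_term(x)
}

#' Optimal-string-alignment (restricted Damerau-Levenshtein) distance
#'
#' Edit distance counting insertions, deletions, substitutions and
#' transpositions of adjacent characters. Used by the local backbone's
#' fuzzy lookup; `b` may be a vector.
#'
#' @param a single string.
#' @param b character vector.
#' @return integer vector of distances.
#' @export
osa_distance <- function(a, b) {
  vapply(b, function(s) osa1(a, s), integer(1), USE.NAMES = FALSE)
}

osa1 <- function(a, b) {
  if (is.na(a) || is.na(b)) return(NA_integer_)
  u <- utf8ToInt(a); v <- utf8ToInt(b)
  n <- length(u); m <- length(v)
  if (n == 0) return(m)
  if (m == 0) return(n)
  if (abs(n - m) > 6) return(abs(n - m))  # cheap lower bound, still exact >2
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in 1:n) {
    for (j in 1:m) {
      cost <- if (u[i] == v[j]) 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L, d[i, j] + cost)
      if (i > 1 && j > 1 && u[i] == v[j - 1] && u[i - 1] == v[j]) {
        d[i + 1, j + 1] <- min(d[i + 1, j + 1], d[i - 1, j - 1] + 1L)
      }
    }
  }
  d[n + 1, m + 1]
}

# ---- cache-backed GBIF species-match adapter -------------------------------

#' Cache-backed GBIF species-match backbone
#'
#' Queries the GBIF species-match web service and persists every response
#' in an append-only JSON-lines cache keyed by (query, hints), so that a
#' completed run is reproducible without network access. With
#' `offline = TRUE` only cached responses are served; an uncached query
#' raises a retryable lookup error (distinct from an unmatched name).
#'
#' @param cache_path JSON-lines cache file (created if absent).
#' @param offline never touch the network, serve the cache only.
#' @param base_url service endpoint.
#' @return a `taxonomy_backbone` of type `"gbif_cached"`.
#' @export
gbif_backbone <- function(cache_path, offline = FALSE,
                          base_url = "https://api.gbif.org/v1/species/match") {
  cache <- list()
  if (file.exists(cache_path)) {
    lines <- readr::read_lines(cache_path)
    lines <- lines[!startsWith(lines, "#") & lines != ""]
    for (ln in lines) {
      e <- jsonlite::fromJSON(ln)
      cache[[e$key]] <- e
    }
  }
  structure(list(type = "gbif_cached", cache = cache, cache_path = cache_path,
                 offline = offline, base_url = base_url),
            class = "taxonomy_backbone")
}

gbif_cache_key <- function(name, kingdom = NA_character_) {
  k <- if (is.null(kingdom) || is.na(kingdom)) "" else tolower(kingdom)
  paste0(normalize_match_name(name), "|", k)
}

gbif_cached_lookup <- function(backbone, name, fuzzy, kingdom = NA_character_) {
  key <- gbif_cache_key(name, kingdom)
  hit <- backbone$cache[[key]] %||% backbone$cache[[gbif_cache_key(name)]]
  if (is.null(hit)) {
    if (backbone$offline) {
      rlang::abort(sprintf("backbone unavailable for query '%s' (offline, not cached)", name),
                   class = "aliendist_lookup_error")
    }
    resp <- tryCatch({
      url <- paste0(backbone$base_url, "?name=", utils::URLencode(name, reserved = TRUE),
                    if (!is.na(kingdom)) paste0("&kingdom=", utils::URLencode(kingdom)))
      jsonlite::fromJSON(url)
    }, error = function(e) {
      rlang::abort(sprintf("backbone unavailable for query '%s': %s", name, conditionMessage(e)),
                   class = "aliendist_lookup_error")
    })
    hit <- list(key = key, query = name, response = resp)
    con <- file(backbone$cache_path, open = "a", encoding = "UTF-8")
    writeLines(jsonlite::toJSON(hit, auto_unbox = TRUE), con)
    close(con)
  }
  gbif_response_entries(hit$response, fuzzy)
}

# Convert one cached species-match response into backbone-entry rows.
gbif_response_entries <- function(r, fuzzy) {
  empty <- tibble::as_tibble(setNames(
    rep(list(character(0)), length(BACKBONE_COLS)), BACKBONE_COLS))
  empty$usage_key <- integer(0); empty$accepted_usage_key <- integer(0)
  if (fuzzy) empty$confidence <- integer(0)
  if (is.null(r) || identical(r$matchType, "NONE")) return(empty)
  is_fuzzy <- identical(r$matchType, "FUZZY")
  if (fuzzy != is_fuzzy) return(empty)
  sci <- r$scientificName %||% r$canonicalName
  row <- tibble::tibble(
    usage_key = as.integer(r$usageKey),
    scientific_name = sci,
    canonical_name = r$canonicalName %||% strip_authority(sci),
    authorship = stringr::str_squish(stringr::str_remove(
      sci, stringr::fixed(r$canonicalName %||% ""))),
    rank = r$rank %||% NA_character_,
    status = if (identical(r$status, "SYNONYM")) "SYNONYM" else
      if (identical(r$status, "DOUBTFUL")) "DOUBTFUL" else "ACCEPTED",
    accepted_usage_key = as.integer(r$acceptedUsageKey %||% r$usageKey),
    kingdom = r$kingdom %||% NA_character_, phylum = r$phylum %||% NA_character_,
    class = r$class %||% NA_character_, order = r$order %||% NA_character_,
    family = r$family %||% NA_character_, genus = r$genus %||% NA_character_,
    species = r$species %||% NA_character_
  )
  if (fuzzy) row$confidence <- as.integer(r$confidence %||% 0L)
  row
}
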