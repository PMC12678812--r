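# The location reference system: a set of named, non-overlapping polygons
# with alternative spellings, subdivisions (for up-scaling state/province
# records), and one or more regional aggregation schemes. Source place
# names are standardized against it; range maps are overlaid on it.

#' Load the location reference system
#'
#' Joins a polygon layer to the location translation table. The polygon
#' layer is delimited text with columns `location` and `wkt` (POLYGON /
#' MULTIPOLYGON, WGS84 lon/lat). The translation table has columns
#' `location`, `locationID`, `alternatives`, `subdivisions` (both
#' `"; "`-separated, may be empty) and one column per aggregation scheme;
#' any column beyond the four fixed ones is treated as a scheme.
#'
#' Distinct locations must not overlap: pairwise interior intersection
#' area above `overlap_tol` square degrees is a configuration error
#' naming the offending pair. Boundary contact is allowed.
#'
#' @param polygon_path path to the WKT polygon layer.
#' @param translation_path path to the location translation table.
#' @param overlap_tol maximal tolerated pairwise interior overlap
#'   (square degrees).
#' @return a `location_table`: tibble with columns `location`,
#'   `locationID`, `alternatives` (list), `subdivisions` (list), one
#'   column per scheme, and `geometry` (list of `adist_geom`).
#' @export
load_locations <- function(polygon_path, translation_path, overlap_tol = 1e-6) {
  for (p in c(polygon_path, translation_path)) {
    if (!file.exists(p)) abort_config(sprintf("location input not found: %s", p))
  }
  polys <- readr::read_csv(polygon_path, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  trans <- readr::read_csv(translation_path, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  need <- c("location", "locationID")
  miss <- setdiff(need, names(trans))
  if (length(miss)) abort_schema(paste("location translation table: missing column(s)",
                                       paste(miss, collapse = ", ")))
  if (!all(c("location", "wkt") %in% names(polys))) {
    abort_schema("polygon layer must have columns 'location' and 'wkt'")
  }
  orphans <- setdiff(polys$location, trans$location)
  if (length(orphans)) {
    abort_config(paste("polygon features with no translation-table row:",
                       paste(orphans, collapse = ", ")))
  }
  if (anyDuplicated(trans$locationID)) {
    abort_config("duplicate locationID in translation table")
  }
  fixed <- c("location", "locationID", "alternatives", "subdivisions")
  schemes <- setdiff(names(trans), fixed)
  if (!"alternatives" %in% names(trans)) trans$alternatives <- NA_character_
  if (!"subdivisions" %in% names(trans)) trans$subdivisions <- NA_character_
  tbl <- trans |>
    dplyr::mutate(
      locationID = as.integer(.data$locationID),
      alternatives = purrr::map2(
        purrr::map(empty_to_na(.data$alternatives), split_composite),
        .data$location, ~ unique(c(.y, .x))),
      subdivisions = purrr::map(empty_to_na(.data$subdivisions),
                                split_composite)
    ) |>
    dplyr::left_join(polys, by = "location") |>
    dplyr::mutate(geometry = purrr::map(.data$wkt, ~ if (is.na(.x)) NULL else parse_wkt(.x))) |>
    dplyr::select(-"wkt")
  check_location_overlaps(tbl, overlap_tol)
  structure(tbl, schemes = schemes, class = c("location_table", class(tbl)))
}

check_location_overlaps <- function(tbl, tol) {
  has_geom <- which(!purrr::map_lgl(tbl$geometry, is.null))
  if (length(has_geom) < 2) return(invisible(TRUE))
  combs <- utils::combn(has_geom, 2)
  for (k in seq_len(ncol(combs))) {
    i <- combs[1, k]; j <- combs[2, k]
    a <- geom_intersection_area(tbl$geometry[[i]], tbl$geometry[[j]])
    if (a > tol) {
      rlang::abort(sprintf("locations '%s' and '%s' overlap (area %.3g deg^2)",
                           tbl$location[i], tbl$location[j], a),
                   class = "aliendist_geometry_error")
    }
  }
  invisible(TRUE)
}

# Build the normalized-name lookup index: name/alternative keys map to the
# location itself, subdivision keys up-scale to the parent location.
# A key claimed by two locations is a configuration defect.
location_index <- function(locations) {
  idx <- attr(locations, "adist_index", exact = TRUE)
  if (!is.null(idx)) return(idx)
  direct <- tibble::tibble(
    key = normalize_term(unlist(locations$alternatives)),
    location = rep(locations$location, lengths(locations$alternatives)),
    via = "name"
  )
  subs <- tibble::tibble(
    key = normalize_term(unlist(locations$subdivisions)),
    location = rep(locations$location, lengths(locations$subdivisions)),
    via = "subdivision"
  )
  idx <- dplyr::bind_rows(direct, subs) |>
    dplyr::distinct(.data$key, .data$location, .data$via)
  amb <- idx |> dplyr::distinct(.data$key, .data$location) |>
    dplyr::count(.data$key) |> dplyr::filter(.data$n > 1)
  if (nrow(amb)) {
    abort_config(paste("ambiguous location name(s) mapping to multiple locations:",
                       paste(amb$key, collapse = ", ")))
  }
  # a key that is both a name and a subdivision of the same location: keep name
  idx |> dplyr::arrange(.data$key, .data$via) |>
    dplyr::distinct(.data$key, .keep_all = TRUE)
}

#' Standardize verbatim place names
#'
#' Match order per name: (1) normalized equality against a standardized
#' location name or alternative spelling; (2) normalized equality against
#' a subdivision, which up-scales the record to the parent location;
#' (3) otherwise unmatched (`NA`), reported for review.
#'
#' @param verbatim character vector of place names.
#' @param locations a `location_table` from [load_locations()].
#' @return tibble with columns `location_verbatim`, `location`,
#'   `locationID`, `matched_via` (`"name"`, `"subdivision"` or `NA`).
#' @export
#' @examples \dontrun{standardize_location("Bavaria", locs) # -> Germany}
standardize_location <- function(verbatim, locations) {
  idx <- location_index(locations)
  key <- normalize_term(verbatim)
  hit <- match(key, idx$key)
  tibble::tibble(
    location_verbatim = as.character(verbatim),
    location = idx$location[hit],
    locationID = locations$locationID[match(idx$location[hit], locations$location)],
    matched_via = idx$via[hit]
  )
}

#' Convert range-map features into checklist records
#'
#' Discards features whose origin code is not in `origin_keep`, then emits
#' one raw record per (feature, location) pair whose geometries intersect
#' with positive area -- boundary contact alone never creates a presence.
#' With `min_fraction > 0`, an intersection must additionally cover at
#' least that fraction of the location's area (equal-area computation) to
#' count, guarding against coarse range maps overhanging borders.
#' Duplicate (taxon, location, origin) combinations collapse to one
#' record; invalid geometries are skipped and logged.
#'
#' @param features tibble with columns `taxon_verbatim`, `wkt` (or
#'   `geometry` list-column), `origin_code`, `source_name`.
#' @param locations a `location_table`.
#' @param origin_keep character set of origin codes to keep
#'   (e.g. `c("native", "reintroduced")`).
#' @param min_fraction minimal intersection / location-area fraction.
#' @return raw-record tibble; attribute `"skipped"` is a tibble of
#'   dropped invalid features.
#' @export
overlay_range_maps <- function(features, locations,
                               origin_keep = c("native", "reintroduced"),
                               min_fraction = 0) {
  stopifnot(length(origin_keep) > 0)
  if (!"geometry" %in% names(features)) {
    features$geometry <- purrr::map(features$wkt,
                                    ~ tryCatch(parse_wkt(.x), error = function(e) NULL))
  }
  keep <- normalize_term(features$origin_code) %in% normalize_term(origin_keep)
  features <- features[keep, , drop = FALSE]
  valid <- purrr::map_lgl(features$geometry, ~ !is.null(.x) && geom_is_valid(.x))
  skipped <- features[!valid, c("taxon_verbatim", "source_name"), drop = FALSE]
  features <- features[valid, , drop = FALSE]
  loc_keep <- !purrr::map_lgl(locations$geometry, is.null)
  loc <- locations[loc_keep, , drop = FALSE]
  loc_area <- purrr::map_dbl(loc$geometry, geom_area, equal_area = TRUE)

  rows <- purrr::pmap(
    list(features$taxon_verbatim, features$geometry,
         features$origin_code, features$source_name),
    function(taxon, geom, origin, src) {
      hits <- purrr::map_lgl(seq_len(nrow(loc)), function(i) {
        if (!geom_overlaps(geom, loc$geometry[[i]])) return(FALSE)
        if (min_fraction <= 0) return(TRUE)
        a <- geom_intersection_area(geom, loc$geometry[[i]], equal_area = TRUE)
        a / loc_area[i] >= min_fraction
      })
      if (!any(hits)) return(NULL)
      raw_records(source_name = src, taxon_verbatim = taxon,
                  location_verbatim = loc$location[hits],
                  establishment_verbatim = origin)
    })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) out <- raw_records(character(0), character(0), character(0))
  out <- dplyr::distinct(out)
  attr(out, "skipped") <- tibble::as_tibble(skipped)
  out
}

#' Regional aggregation label of locations
#'
#' Looks up the region each location belongs to under a named aggregation
#' scheme. Scheme membership partitions the location set: every location
#' carries exactly one label per scheme.
#'
#' @param locations a `location_table`.
#' @param scheme scheme name (one of `aggregation_schemes(locations)`).
#' @param location optional character vector of location names to look up;
#'   default all.
#' @return tibble with columns `location`, `region`.
#' @export
aggregate_region <- function(locations, scheme, location = NULL) {
  schemes <- aggregation_schemes(locations)
  if (!scheme %in% schemes) {
    abort_config(sprintf("unknown aggregation scheme '%s'; available: %s",
                         scheme, paste(schemes, collapse = ", ")))
  }
  out <- tibble::tibble(location = locations$location,
                        region = locations[[scheme]])
  if (!is.null(location)) {
    missing <- setdiff(location, out$location)
    if (length(missing)) abort_config(paste("unknown location(s):",
                                            paste(missing, collapse = ", ")))
    out <- out[match(location, out$location), , drop = FALSE]
  }
  out
}

#' Aggregation schemes available in a location table
#' @param locations a `location_table`.
#' @return character vector of scheme names.
#' @export
aggregation_schemes <- function(locations) attr(locations, "schemes", exact = TRUE) %||% character(0)
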