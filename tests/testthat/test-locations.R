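test_that("the location layer loads with memberships and disjoint squares", {
  fx <- make_grid_locations()
  locs <- fx$locations
  expect_equal(nrow(locs), 4)
  expect_equal(locs$locationID[locs$location == "Aland"], 58L)
  expect_setequal(aggregation_schemes(locs), c("custom", "realm"))
  # edge-sharing squares load fine: interior overlap only is forbidden
  expect_true(all(vapply(locs$geometry, geom_is_valid, logical(1))))
})

test_that("a polygon without a translation row fails to load, as does interior overlap", {
  fx <- make_grid_locations()
  polys <- readr::read_csv(fx$polygon_path, show_col_types = FALSE)
  polys$location[1] <- "Nowhere"
  p2 <- file.path(fx$dir, "polys_bad.csv"); readr::write_csv(polys, p2)
  expect_error(load_locations(p2, fx$translation_path), "Nowhere")

  polys <- readr::read_csv(fx$polygon_path, show_col_types = FALSE)
  polys$wkt[2] <- "POLYGON ((0.5 0, 2 0, 2 1, 0.5 1, 0.5 0))"  # overlaps Aland
  p3 <- file.path(fx$dir, "polys_overlap.csv"); readr::write_csv(polys, p3)
  expect_error(load_locations(p3, fx$translation_path),
               class = "aliendist_geometry_error")
})

test_that("place names match by name, alternative, then subdivision up-scaling", {
  locs <- make_grid_locations()$locations
  got <- standardize_location(
    c("Aland", "alandia", "  CORVIA isles ", "North Aland", "Bavaria-like", "Atlantis"),
    locs)
  expect_equal(got$location,
               c("Aland", "Aland", "Corvia", "Aland", "Borduna", NA))
  expect_equal(got$locationID, c(58L, 58L, 31L, 58L, 12L, NA))
  expect_equal(got$matched_via,
               c("name", "name", "name", "subdivision", "subdivision", NA))
})

test_that("a name claimed by two locations is a configuration error", {
  fx <- make_grid_locations()
  trans <- readr::read_csv(fx$translation_path, show_col_types = FALSE)
  trans$alternatives[2] <- "Alandia"  # already an alternative of Aland
  tp <- file.path(fx$dir, "trans_amb.csv"); readr::write_csv(trans, tp)
  locs <- load_locations(fx$polygon_path, tp)
  expect_error(standardize_location("Alandia", locs), class = "aliendist_config_error")
})

test_that("aggregation schemes partition the locations; unknown schemes error", {
  locs <- make_grid_locations()$locations
  for (scheme in aggregation_schemes(locs)) {
    lab <- aggregate_region(locs, scheme)
    expect_equal(nrow(lab), nrow(locs))
    expect_false(any(is.na(lab$region)))
  }
  expect_equal(aggregate_region(locs, "custom", "Aland")$region, "West")
  expect_error(aggregate_region(locs, "foo"), class = "aliendist_config_error")
})

test_that("range-map overlay keeps allowed origins and positive-area intersections only", {
  locs <- make_grid_locations()$locations
  feats <- tibble::tibble(
    taxon_verbatim = c("Sp one", "Sp two", "Sp three", "Sp four", "Sp five"),
    wkt = c(
      "POLYGON ((0.2 0.2, 0.8 0.2, 0.8 0.8, 0.2 0.8, 0.2 0.2))",  # inside Aland
      "POLYGON ((0.5 0.2, 1.5 0.2, 1.5 0.8, 0.5 0.8, 0.5 0.2))",  # spans Aland+Borduna
      "POLYGON ((1 0.2, 1.6 0.2, 1.6 0.8, 1 0.8, 1 0.2))",        # touches Aland edge only
      "POLYGON ((0.2 0.2, 0.8 0.2, 0.8 0.8, 0.2 0.8, 0.2 0.2))",  # wrong origin
      "POLYGON ((0 0, 1 1, 0 0))"                                  # invalid
    ),
    origin_code = c("native", "native", "reintroduced", "introduced", "native"),
    source_name = "RM")
  rec <- overlay_range_maps(feats, locs, origin_keep = c("native", "reintroduced"))
  expect_setequal(rec$location_verbatim[rec$taxon_verbatim == "Sp one"], "Aland")
  expect_setequal(rec$location_verbatim[rec$taxon_verbatim == "Sp two"],
                  c("Aland", "Borduna"))
  expect_setequal(rec$location_verbatim[rec$taxon_verbatim == "Sp three"], "Borduna")
  expect_false("Sp four" %in% rec$taxon_verbatim)
  expect_false("Sp five" %in% rec$taxon_verbatim)
  expect_equal(attr(rec, "skipped")$taxon_verbatim, "Sp five")
  expect_true(all(rec$establishment_verbatim %in% c("native", "reintroduced")))
})

test_that("overlay agrees with the raster point-membership oracle", {
  locs <- make_grid_locations()$locations
  feats <- generate_range_features(6, seed = 99, extent = 2)
  for (i in seq_len(nrow(feats))) {
    g <- parse_wkt(feats$wkt[i])
    rec <- overlay_range_maps(
      tibble::tibble(taxon_verbatim = "T", wkt = feats$wkt[i],
                     origin_code = "native", source_name = "RM"), locs)
    expect_true(setequal(rec$location_verbatim, oracle_overlay_raster(g, locs)),
                info = paste("feature", i))
  }
})
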