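# Shared fixture builders and independent oracles.

# A 2x2 grid of unit-square locations with alternatives, subdivisions and
# two aggregation schemes, written to files and loaded through the module
# under test.
make_grid_locations <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  trans <- tibble::tibble(
    location = c("Aland", "Borduna", "Corvia", "Dunmar"),
    locationID = c(58L, 12L, 31L, 44L),
    alternatives = c("Alandia", "", "Corvia Isles", ""),
    subdivisions = c("North Aland; South Aland", "Bavaria-like", "", ""),
    custom = c("West", "West", "East", "East"),
    realm = c("Boreal", "Boreal", "Austral", "Austral")
  )
  polys <- tibble::tibble(
    location = trans$location,
    wkt = c("POLYGON ((0 0, 1 0, 1 1, 0 1, 0 0))",
            "POLYGON ((1 0, 2 0, 2 1, 1 1, 1 0))",
            "POLYGON ((0 1, 1 1, 1 2, 0 2, 0 1))",
            "POLYGON ((1 1, 2 1, 2 2, 1 2, 1 1))")
  )
  pp <- file.path(dir, "polys.csv"); tp <- file.path(dir, "trans.csv")
  readr::write_csv(polys, pp); readr::write_csv(trans, tp)
  list(locations = load_locations(pp, tp), polygon_path = pp,
       translation_path = tp, dir = dir)
}

# Fine-raster overlay oracle: a location intersects a feature iff at least
# one raster cell center of the location's bounding box lies in both
# geometries. Resolution h in degrees.
oracle_overlay_raster <- function(geom, locations, h = 0.05) {
  hits <- character(0)
  for (i in seq_len(nrow(locations))) {
    g <- locations$geometry[[i]]
    if (is.null(g)) next
    bb <- aliendist:::geom_bbox(g)
    xs <- seq(bb[1] + h / 2, bb[3] - h / 2, by = h)
    ys <- seq(bb[2] + h / 2, bb[4] - h / 2, by = h)
    found <- FALSE
    for (x in xs) {
      if (found) break
      for (y in ys) {
        if (point_in_geom(x, y, g) && point_in_geom(x, y, geom)) {
          found <- TRUE; break
        }
      }
    }
    if (found) hits <- c(hits, locations$location[i])
  }
  hits
}

# Random standardized-record tables for merge oracle comparisons.
random_std_records <- function(n, seed) {
  withr::with_seed(seed, {
    taxa <- paste("Taxon", sample(letters[1:8], n, replace = TRUE))
    loc_id <- sample(c(58L, 12L, 31L, 44L), n, replace = TRUE)
    loc <- c(`58` = "Aland", `12` = "Borduna", `31` = "Corvia", `44` = "Dunmar")[as.character(loc_id)]
    em <- sample(c("native", "introduced", "uncertain", "vagrant", NA), n,
                 replace = TRUE, prob = c(.3, .35, .15, .05, .15))
    tibble::tibble(
      source_name = sample(c("S1", "S2", "S3"), n, replace = TRUE),
      taxon = taxa, location = unname(loc), locationID = loc_id,
      establishmentMeans = em,
      occurrenceStatus = sample(c("present", "absent", NA), n, replace = TRUE),
      degreeOfEstablishment = ifelse(em %in% "introduced" & runif(n) < .4,
                                     sample(c("established", "invasive"), n, replace = TRUE), NA),
      pathway = ifelse(em %in% "introduced" & runif(n) < .3,
                       sample(c("corridor", "unaided"), n, replace = TRUE), NA),
      habitat = sample(c("marine", "freshwater; marine", NA), n, replace = TRUE),
      eventDate = ifelse(runif(n) < .5, sample(1800:2000, n, replace = TRUE), NA_integer_)
    )
  })
}

fixture_citations <- c(S1 = "Source One (2020)", S2 = "Source Two (2021)",
                       S3 = "Source Three (2022)")
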