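test_that("fixture generation is byte-identical for the same seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  spec <- fixture_spec(seed = 77, n_true_taxa = 30)
  generate_fixture_set(spec, d1)
  generate_fixture_set(spec, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_equal(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in setdiff(f1, "output")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("backbone composition follows the configured fractions", {
  spec <- fixture_spec(seed = 3, n_true_taxa = 50, synonym_fraction = 0.2,
                       homonym_fraction = 0.1, misspelling_fraction = 0)
  bb <- generate_backbone(spec, withr::local_tempdir())
  expect_equal(sum(bb$table$status == "SYNONYM"), 10)
  syn <- bb$table[bb$table$status == "SYNONYM", ]
  acc_keys <- bb$table$usage_key[bb$table$status == "ACCEPTED"]
  expect_true(all(syn$accepted_usage_key %in% acc_keys))
  # homonym pairs share a canonical name across two kingdoms
  hom <- bb$manifest[bb$manifest$kind == "homonym", ]
  for (v in hom$verbatim) {
    entries <- bb$table[bb$table$canonical_name == v, ]
    expect_equal(nrow(entries), 2)
    expect_equal(dplyr::n_distinct(entries$kingdom), 2)
  }
  # all-zero fractions: accepted rows only
  bb0 <- generate_backbone(fixture_spec(seed = 3, n_true_taxa = 50,
                                        synonym_fraction = 0, homonym_fraction = 0,
                                        misspelling_fraction = 0),
                           withr::local_tempdir())
  expect_equal(nrow(bb0$table), 50)
  expect_true(all(bb0$table$status == "ACCEPTED"))
})

test_that("fraction and grid invariants are enforced", {
  expect_error(fixture_spec(synonym_fraction = 0.6, homonym_fraction = 0.3,
                            misspelling_fraction = 0.2),
               class = "aliendist_config_error")
  expect_error(fixture_spec(n_locations = 7), class = "aliendist_config_error")
})

test_that("generated locations are pairwise disjoint and schemes partition them", {
  spec <- fixture_spec(seed = 5)
  lx <- generate_locations(spec, withr::local_tempdir())
  locs <- load_locations(lx$polygon_path, lx$translation_path)  # overlap-checked
  expect_equal(nrow(locs), 9)
  for (scheme in aggregation_schemes(locs)) {
    expect_false(any(is.na(aggregate_region(locs, scheme)$region)))
  }
  # each location name is among its own alternatives
  idx <- aliendist:::location_index(locs)
  expect_true(all(normalize_term(locs$location) %in% idx$key))
})

test_that("planted anomalies are all accounted for in the ledger", {
  fx <- generate_fixture_set(fixture_spec(seed = 11), withr::local_tempdir())
  led <- fx$sources$ledger
  expect_setequal(led$unmatched_terms$field,
                  c("establishmentMeans", "pathway", "eventDate"))
  expect_true("introduced; uncertain" %in% led$records$establishmentMeans)
  expect_true(any(led$taxa$GBIFmatchtype == "FUZZY", na.rm = TRUE))
  expect_true(any(led$taxa$GBIFstatus == "SYNONYM"))
  expect_true(any(led$taxa$GBIFnote == "Homonym in GBIF", na.rm = TRUE))
  expect_true(any(led$taxa$GBIFstatus == "MISSING"))
  expect_setequal(unique(led$exclusions$reason),
                  c("unmatched location", "missing establishmentMeans"))
})
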