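test_that("vocabularies map variants to canonical terms and self-map canonicals", {
  v <- vocabulary("habitat", c(sea = "marine", land = "terrestrial"))
  expect_setequal(unique(v$canonical),
                  c("brackish", "freshwater", "marine", "terrestrial"))
  expect_equal(v$canonical[v$variant == "sea"], "marine")
  # every canonical term maps to itself
  expect_true(all(c("brackish", "freshwater", "marine", "terrestrial") %in% v$variant))
})

test_that("a variant pointing at an unknown canonical term is rejected", {
  expect_error(vocabulary("habitat", c(sky = "aerial")), class = "aliendist_config_error")
})

test_that("a variant mapped to two canonical terms is a configuration error", {
  expect_error(vocabulary("habitat", c(sea = "marine", Sea = "brackish")),
               class = "aliendist_config_error")
})

test_that("translation tables round-trip through files", {
  dir <- withr::local_tempdir()
  paths <- write_translation_tables(dir)
  for (field in names(default_vocabularies())) {
    v <- read_translation_table(file.path(dir, paste0(field, ".csv")), field)
    d <- default_vocabularies()[[field]]
    expect_equal(dplyr::arrange(v, variant_norm), dplyr::arrange(d, variant_norm),
                 info = field)
  }
})

test_that("reading a table without the canonical column is a schema error", {
  p <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(x = "a", y = "b"), p)
  expect_error(read_translation_table(p, "habitat"), class = "aliendist_schema_error")
})
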